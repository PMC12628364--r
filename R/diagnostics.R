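#' Within-subject variance discrepancy statistic
#'
#' Sample variance (denominator n-1) of a subject's completed outcome
#' series around the subject's own mean — the default discrepancy for the
#' posterior predictive imputation check.
#'
#' @param series Numeric vector of length >= 2.
#' @return Scalar variance.
#' @export
ws_variance_statistic <- function(series) {
  if (length(series) < 2) stop("need >= 2 values for a variance statistic")
  stats::var(series)
}

# Per-row conditional means and log-variances for every retained draw,
# as K x S matrices (rows of `data` by draws).
predictor_matrices <- function(fit, data) {
  d <- fit$draws
  S <- nrow(d)
  i <- data$subject
  X <- as.matrix(data[, fit$mean_covariates, drop = FALSE])
  B <- t(d[, paste0("beta_", fit$mean_covariates), drop = FALSE])
  MU <- matrix(d[, "beta0"], nrow(data), S, byrow = TRUE) + X %*% B
  if (fit$kind == "rilm") {
    MU <- MU + t(fit$effects$v0)[i, , drop = FALSE]
    LV <- matrix(d[, "alpha0"], nrow(data), S, byrow = TRUE)
  } else {
    LV <- matrix(d[, "alpha0"], nrow(data), S, byrow = TRUE)
    if (length(fit$var_covariates)) {
      Xa <- as.matrix(data[, fit$var_covariates, drop = FALSE])
      A <- t(d[, paste0("alpha_", fit$var_covariates), drop = FALSE])
      LV <- LV + Xa %*% A
    }
    if (fit$kind == "mels") {
      MU <- MU + t(fit$effects$v0)[i, , drop = FALSE]
      LV <- LV + t(fit$effects$v1)[i, , drop = FALSE]
    } else {
      G <- matrix(d[, "gamma"], nrow(data), S, byrow = TRUE)
      D <- matrix(d[, "delta"], nrow(data), S, byrow = TRUE)
      LAM <- t(fit$effects$lam)[i, , drop = FALSE]
      MU <- MU + t(fit$effects$eta0)[i, , drop = FALSE] + G * LAM
      LV <- LV + t(fit$effects$eta1)[i, , drop = FALSE] + D * LAM
    }
  }
  list(MU = MU, LV = LV)
}

#' Posterior predictive check of the imputation model
#'
#' Completed-data posterior predictive p-values with a per-subject
#' discrepancy. For each of `Lppc` posterior draws, the missing outcomes
#' are imputed conditional on that draw's parameters and subject effects;
#' a full replicate of every scheduled occasion is then simulated from the
#' fitted hierarchy at the same parameter draw with a fresh draw of subject
#' effects; and the indicator \eqn{Q(y^{rep}) \ge Q(y^{com})} is evaluated
#' per subject (ties count as satisfying the inequality). The p-value is
#' the proportion over draws. Values near 0 or 1 flag a discrepancy the
#' model cannot reproduce.
#'
#' @param fit A `posterior_draws` object.
#' @param data The dataset the model was fitted to.
#' @param Q Discrepancy mapping a completed subject series to a scalar.
#' @param Lppc Number of simulation draws (posterior draws are recycled by
#'   resampling when `Lppc` exceeds the retained count).
#' @param seed Integer seed.
#' @return A `ppc_result`: data.frame `p_values` (subject, p_com), the
#'   statistic name, `Lppc`, and any excluded subjects.
#' @export
ppc_pvalue <- function(fit, data, Q = ws_variance_statistic, Lppc = 1000,
                       seed = 1L) {
  stopifnot(inherits(fit, "posterior_draws"))
  for (cc in unique(c(fit$mean_covariates, fit$var_covariates)))
    if (anyNA(data[[cc]]))
      stop("covariate '", cc, "' has missing values; complete it first ",
           "(e.g. with the pooled imputation) before the predictive check")
  set.seed(as.integer(seed))
  N <- n_subjects(data)
  n_i <- tabulate(data$subject, N)
  excluded <- which(n_i < 2)
  if (length(excluded))
    message("excluding subject(s) with < 2 scheduled occasions: ",
            paste(excluded, collapse = ", "))
  S <- nrow(fit$draws)
  idx <- sample.int(S, Lppc, replace = Lppc > S)
  pr <- predictor_matrices(fit, data)
  y <- data[[fit$outcome]]
  miss <- is.na(y)
  K <- nrow(data)
  ge_count <- rep(0L, N)
  use_q <- if (is.function(Q)) Q else stop("Q must be a function")
  q_safe <- function(v) if (length(v) < 2) NA_real_ else use_q(v)
  per_subject_q <- function(v) as.numeric(tapply(v, data$subject, q_safe))
  for (l in idx) {
    mu <- pr$MU[, l]; sdv <- exp(pr$LV[, l] / 2)
    ycom <- y
    ycom[miss] <- stats::rnorm(sum(miss), mu[miss], sdv[miss])
    # replicate: fresh subject effects from the hierarchy at this draw
    params_l <- params_from_draw(fit, l)
    eff_rep <- draw_subject_effects(params_l, N)
    prr <- row_predictors(params_l, data, eff_rep)
    yrep <- stats::rnorm(K, prr$mu, exp(prr$log_var / 2))
    cmp <- per_subject_q(yrep) >= per_subject_q(ycom)
    cmp[is.na(cmp)] <- FALSE   # subjects excluded below
    ge_count <- ge_count + as.integer(cmp)
  }
  pv <- data.frame(subject = seq_len(N), p_com = ge_count / length(idx))
  if (length(excluded)) pv <- pv[-excluded, ]
  structure(list(p_values = pv, statistic = deparse(substitute(Q)),
                 Lppc = Lppc, excluded = excluded, model = fit$kind),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("<ppc_result> %s, %d subjects, Lppc = %d\n",
              toupper(x$model), nrow(x$p_values), x$Lppc))
  print(summary(x$p_values$p_com))
  invisible(x)
}

# log(mean(exp(x))) along rows, stable.
row_log_mean_exp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowMeans(exp(M - mx)))
}

#' Compare model fits by expected log predictive density
#'
#' Pointwise predictive log density per observed outcome, conditional on
#' the sampled subject effects (the convention for hierarchical
#' leave-one-out), aggregated in-sample and by leave-one-out importance
#' sampling: \eqn{\widehat{elpd}_{loo,i} = -\log \frac{1}{S}\sum_s 1/p(y_i
#' \mid \theta^{(s)})}. Importance weights that concentrate on few draws
#' are flagged per point (`n_flagged`: points whose largest normalized
#' weight exceeds 0.5). Totals are sums of pointwise contributions; higher
#' is better.
#'
#' @param fits Named list of `posterior_draws` objects fitted to the same
#'   observed rows of `data`.
#' @param data The common dataset.
#' @return An `elpd_result`: per-model table (`elpd_loo`, `elpd_insample`,
#'   `se`, `n_flagged`) and pairwise LOO differences with standard errors.
#' @export
elpd_compare <- function(fits, data) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, `[[`, "", "kind")
  outcome <- fits[[1]]$outcome
  obs <- which(!is.na(data[[outcome]]))
  dobs <- data[obs, , drop = FALSE]
  y <- dobs[[outcome]]
  point <- list()
  tab <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    stopifnot(identical(fit$outcome, outcome))
    pr <- predictor_matrices(fit, dobs)
    LL <- stats::dnorm(y, pr$MU, exp(pr$LV / 2), log = TRUE)
    in_i <- row_log_mean_exp(LL)
    loo_i <- -row_log_mean_exp(-LL)
    W <- exp(-LL - apply(-LL, 1, max))
    max_w <- apply(W / rowSums(W), 1, max)
    point[[nm]] <- loo_i
    tab[[nm]] <- data.frame(model = nm,
                            elpd_loo = sum(loo_i),
                            elpd_insample = sum(in_i),
                            se = sqrt(length(loo_i) * stats::var(loo_i)),
                            n_flagged = sum(max_w > 0.5))
  }
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  pw <- list()
  nms <- names(fits)
  if (length(nms) > 1) {
    for (a in seq_along(nms)[-length(nms)]) for (b in (a + 1):length(nms)) {
      dd <- point[[nms[a]]] - point[[nms[b]]]
      pw[[paste(nms[a], nms[b])]] <- data.frame(
        model_a = nms[a], model_b = nms[b],
        elpd_diff = sum(dd), se_diff = sqrt(length(dd) * stats::var(dd)))
    }
    pw <- do.call(rbind, pw)
    rownames(pw) <- NULL
  } else pw <- NULL
  structure(list(table = tab, pairwise = pw, pointwise = point,
                 n_points = length(y)),
            class = "elpd_result")
}

#' @export
print.elpd_result <- function(x, ...) {
  cat(sprintf("<elpd_result> %d observed points\n", x$n_points))
  print(transform(x$table, elpd_loo = round(elpd_loo, 2),
                  elpd_insample = round(elpd_insample, 2),
                  se = round(se, 2)), row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("\nPairwise LOO differences:\n")
    print(transform(x$pairwise, elpd_diff = round(elpd_diff, 2),
                    se_diff = round(se_diff, 2)), row.names = FALSE)
  }
  invisible(x)
}
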