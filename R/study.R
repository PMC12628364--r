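#' Simulation-study metrics
#'
#' Small pure functions implementing the study's evaluation criteria.
#'
#' `bias()` is the mean deviation of the replicate estimates from the true
#' value. `coverage()` is the percentage of interval estimates that contain
#' the truth, with strict inequalities (an interval whose bound equals the
#' truth does not cover). `imputation_error()` is the mean squared
#' difference between the completed and true values over all scheduled
#' cells — observed cells contribute zero. `difference_ratio()` compares the
#' best and worst imputation model as \eqn{100 (worst - best) / worst}.
#'
#' @param estimates Numeric vector of per-replicate estimates.
#' @param truth True parameter value.
#' @return `bias()`: scalar mean deviation.
#' @examples
#' bias(c(1, 3), truth = 1)
#' coverage(cbind(lo = c(0, 2), hi = c(2, 3)), truth = 1)
#' @name study_metrics
NULL

#' @rdname study_metrics
#' @export
bias <- function(estimates, truth) {
  if (!length(estimates)) stop("no estimates")
  mean(estimates - truth)
}

#' @rdname study_metrics
#' @param intervals Two-column matrix (or data.frame) of lower/upper bounds.
#' @export
coverage <- function(intervals, truth) {
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L || !nrow(intervals)) stop("malformed intervals")
  if (any(intervals[, 1] >= intervals[, 2])) stop("lower bound >= upper bound")
  100 * mean(intervals[, 1] < truth & truth < intervals[, 2])
}

#' @rdname study_metrics
#' @param completed Completed dataset (e.g. from [pool_mean()]).
#' @param truth_data The generated `ema_dataset` retaining `true_*` columns.
#' @param target Column whose imputation error is computed.
#' @export
imputation_error <- function(completed, truth_data, target = "y") {
  true_col <- paste0("true_", target)
  if (is.null(truth_data[[true_col]]))
    stop("truth dataset lacks column ", true_col)
  yhat <- completed[[target]]
  if (anyNA(yhat)) stop("completed data still has missing ", target)
  mean((yhat - truth_data[[true_col]])^2)
}

#' @rdname study_metrics
#' @param errors_by_model Named numeric vector of per-model mean errors
#'   (>= 2 models); ties are broken by the fixed order rilm, mels, spmels.
#' @export
difference_ratio <- function(errors_by_model) {
  stopifnot(length(errors_by_model) >= 2, !is.null(names(errors_by_model)))
  ord <- c("rilm", "mels", "spmels")
  pos <- match(names(errors_by_model), ord)
  o <- order(pos, na.last = TRUE)
  e <- errors_by_model[o]
  if (all(e == 0)) stop("all errors zero: ratio undefined")
  best <- names(e)[which.min(e)]
  worst <- names(e)[which.max(e)]
  list(best = best, worst = worst,
       ratio = 100 * (max(e) - min(e)) / max(e))
}

# Truth lookup for every parameter a fitted model reports, extending the
# generating-block values with zeros for imputation-model covariates that
# the generative process does not use (day/beep terms), and with the
# calibrated missingness intercept for SPMELS.
truth_for_fit <- function(scenario, kind, block, tau0) {
  tv <- true_values(scenario, kind, block)
  extra_beta <- paste0("beta_", c("day", "beep1", "beep6"))
  extra_alpha <- paste0("alpha_", c("day", "beep1", "beep6"))
  tv <- c(tv, stats::setNames(rep(0, 3), extra_beta))
  if (kind != "rilm")
    tv <- c(tv, stats::setNames(rep(0, 3), extra_alpha))
  if (kind == "spmels") {
    tv <- c(tv, tau0 = tau0,
            stats::setNames(as.numeric(scenario$tau),
                            paste0("tau_", names(scenario$tau))))
  }
  tv
}

intervals_from_fit <- function(fit) {
  if (inherits(fit, "ml_fit"))
    data.frame(parameter = fit$summary$parameter,
               estimate = fit$summary$estimate,
               lower = fit$summary$lower, upper = fit$summary$upper)
  else
    data.frame(parameter = fit$summary$parameter,
               estimate = fit$summary$mean,
               lower = fit$summary$q2.5, upper = fit$summary$q97.5)
}

run_replicate <- function(scenario, tau0, models, L, config, method_rilm,
                          seed_k) {
  data <- generate_dataset(scenario, seed = seed_k, tau0 = tau0)
  x1_cov <- c("x2", "day", "beep1", "beep6")
  y_cov <- c("x1", "x2", "day", "beep1", "beep6")
  imp_x1 <- list(); fits_y <- list()
  est_rows <- list()
  for (kind in models) {
    fx <- fit_model(kind, data, "x1", x1_cov, var_covariates = "x2",
                    method_rilm = method_rilm,
                    config = config, seed = seed_k + 1L)
    dx <- draw_step1(fx, L, seed = seed_k + 2L)
    imp_x1[[kind]] <- impute_variable(data, dx, "x1", seed = seed_k + 3L)
    # x1 and y are missing together, so the y model's likelihood rows all
    # have observed x1 and the fit does not depend on the completed copies;
    # the WS-variance submodel keeps the continuous covariates only, matching
    # the estimands the metrics table reports
    fy <- fit_model(kind, data, "y", y_cov, var_covariates = c("x1", "x2"),
                    method_rilm = method_rilm,
                    config = config, seed = seed_k + 4L)
    fits_y[[kind]] <- fy
    ci <- intervals_from_fit(fy)
    ci$model <- kind
    est_rows[[kind]] <- ci
  }
  err_rows <- list()
  for (x1k in models) {
    for (yk in models) {
      dy <- draw_step1(fits_y[[yk]], L, seed = seed_k + 5L)
      y_copies <- matrix(NA_real_, nrow(data), L)
      for (l in seq_len(L)) {
        dl <- data
        dl$x1 <- imp_x1[[x1k]]$copies[, l]
        one <- structure(dy[l], class = "step1_draws",
                         kind = attr(dy, "kind"), outcome = "y")
        y_copies[, l] <- impute_variable(dl, one, "y",
                                         seed = seed_k + 200L + l)$copies[, 1]
      }
      single <- data; single$y <- y_copies[, 1]
      pooled <- data; pooled$y <- rowMeans(y_copies)
      err_rows[[paste(x1k, yk)]] <- data.frame(
        model_x1 = x1k, model_y = yk,
        mode = c("single", "multiple"),
        error = c(imputation_error(single, data),
                  imputation_error(pooled, data)))
    }
  }
  list(estimates = do.call(rbind, est_rows), errors = do.call(rbind, err_rows))
}

#' Run the simulation study
#'
#' Repeats the full generate / fit / impute cycle `K` times for one
#' scenario: every model kind is fitted for `x1` and for `y`, `x1` is
#' imputed under each x1-model, and `y` is imputed under every
#' (x1-model, y-model) pairing, in both single-imputation (first copy) and
#' multiple-imputation (cellwise mean of L copies) arms. Per-replicate
#' seeds are derived deterministically from `seed`, so replicates are
#' independent and order-invariant. A replicate whose fit fails is retried
#' once with a derived seed, then recorded in `failures` and excluded —
#' never silently dropped.
#'
#' @param scenario An [ema_scenario()].
#' @param K Number of replicates.
#' @param L Imputations per replicate (multiple-imputation arm).
#' @param models Model kinds to compare.
#' @param config [mcmc_config()] for MELS/SPMELS fits.
#' @param method_rilm `"ml"` or `"mcmc"` for RILM Step-1 fits.
#' @param seed Master seed.
#' @return A `study_result` with tidy `estimates` and `errors` tables, the
#'   bias/coverage `metrics` table, per-pairing `error_summary`,
#'   `difference_ratios`, and a `failures` log.
#' @export
run_study <- function(scenario, K = 100, L = 10,
                      models = c("rilm", "mels", "spmels"),
                      config = mcmc_config(), method_rilm = "ml", seed = 1L) {
  stopifnot(K >= 1)
  tau0 <- calibrate_tau0(scenario)
  set.seed(as.integer(seed))
  # headroom below .Machine$integer.max for the small per-step offsets
  rep_seeds <- sample.int(2^31 - 1000, K)
  all_est <- list(); all_err <- list(); failures <- list()
  for (k in seq_len(K)) {
    res <- tryCatch(
      suppressWarnings(run_replicate(scenario, tau0, models, L, config,
                                     method_rilm, rep_seeds[k])),
      error = function(e) e)
    if (inherits(res, "error")) {
      res <- tryCatch(
        suppressWarnings(run_replicate(scenario, tau0, models, L, config,
                                       method_rilm, rep_seeds[k] + 7L)),
        error = function(e) e)
    }
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(replicate = k, message = conditionMessage(res))
      next
    }
    res$estimates$replicate <- k
    res$errors$replicate <- k
    all_est[[k]] <- res$estimates
    all_err[[k]] <- res$errors
  }
  if (!length(all_est)) stop("all replicates failed")
  estimates <- do.call(rbind, all_est)
  errors <- do.call(rbind, all_err)
  rownames(estimates) <- rownames(errors) <- NULL

  # bias / coverage per model x parameter against the scenario's truths
  metrics <- do.call(rbind, lapply(models, function(kind) {
    tv <- truth_for_fit(scenario, kind, "y", tau0)
    em <- estimates[estimates$model == kind, ]
    do.call(rbind, lapply(intersect(unique(em$parameter), names(tv)),
      function(par) {
        ep <- em[em$parameter == par, ]
        data.frame(model = kind, parameter = par, truth = tv[[par]],
                   bias = bias(ep$estimate, tv[[par]]),
                   coverage = coverage(ep[, c("lower", "upper")], tv[[par]]),
                   n_replicates = nrow(ep))
      }))
  }))
  rownames(metrics) <- NULL

  err_sum <- stats::aggregate(error ~ model_x1 + model_y + mode, errors, mean)
  dr <- do.call(rbind, lapply(split(err_sum[err_sum$mode == "multiple", ],
                                    err_sum[err_sum$mode == "multiple", "model_x1"]),
    function(g) {
      r <- difference_ratio(stats::setNames(g$error, g$model_y))
      data.frame(model_x1 = g$model_x1[1], best = r$best, worst = r$worst,
                 ratio = r$ratio)
    }))
  rownames(dr) <- NULL
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(replicate = integer(0), message = character(0))
  if (nrow(failures))
    message(sprintf("%d replicate(s) excluded after one retry", nrow(failures)))
  structure(list(scenario = scenario, K = K, L = L, tau0 = tau0,
                 estimates = estimates, errors = errors, metrics = metrics,
                 error_summary = err_sum, difference_ratios = dr,
                 failures = failures, seed = seed),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> K = %d replicates (%d failed), L = %d\n",
              x$K, nrow(x$failures), x$L))
  cat("\nBias / coverage (y model):\n")
  print(transform(x$metrics, bias = round(bias, 3),
                  coverage = round(coverage, 1)), row.names = FALSE)
  cat("\nMean imputation error by (x1 model, y model):\n")
  print(transform(x$error_summary, error = round(error, 4)),
        row.names = FALSE)
  cat("\nDifference ratios (multiple imputation):\n")
  print(transform(x$difference_ratios, ratio = round(ratio, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Write study tables to a directory as tidy CSV
#'
#' @param study A `study_result`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(study$error_summary, file.path(dir, "errors.csv"),
                   row.names = FALSE)
  utils::write.csv(study$difference_ratios,
                   file.path(dir, "difference_ratios.csv"), row.names = FALSE)
  invisible(dir)
}
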