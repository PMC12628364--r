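#' MCMC sampler configuration
#'
#' Settings for Step-1 posterior sampling. Defaults follow common practice
#' for hierarchical location-scale models; all are overridable. Priors are
#' weakly informative: normal(0, `prior_coef_sd`) on regression, missingness
#' and loading coefficients; half-Cauchy(`prior_scale_scale`) on SDs;
#' uniform(-1, 1) on correlations.
#'
#' @param chains Number of chains.
#' @param adapt Adaptation iterations.
#' @param burn Burn-in iterations after adaptation.
#' @param iter Retained iterations per chain.
#' @param thin Thinning interval.
#' @param rhat_threshold Split-R-hat convergence threshold.
#' @param prior_coef_sd Prior SD of coefficients.
#' @param prior_scale_scale Half-Cauchy scale of SD priors.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 2, adapt = 500, burn = 500, iter = 1000,
                        thin = 1, rhat_threshold = 1.05,
                        prior_coef_sd = 10, prior_scale_scale = 5) {
  structure(list(chains = chains, adapt = adapt, burn = burn, iter = iter,
                 thin = thin, rhat_threshold = rhat_threshold,
                 prior_coef_sd = prior_coef_sd,
                 prior_scale_scale = prior_scale_scale),
            class = "mcmc_config")
}

# JAGS model code per model kind. Two numerical/sampling choices live here:
# the log WS-variance linear predictor is clipped to [-30, 30] inside the
# sampler only (overflow guard during warmup; no effect at convergence), and
# the location submodel is hierarchically centered — subject-constant mean
# covariates (matrix Z) and, for SPMELS, the gamma*lambda term enter the
# random intercept's mean, which decorrelates those coefficients from the
# subject effects and lets JAGS use conjugate updates for them.
jags_code <- function(kind, nz, nr, na_) {
  zterm <- if (nz) " + inprod(Z[i,], betaz)" else ""
  rterm <- if (nr) " + inprod(Xr[k,], betar)" else ""
  aterm <- if (na_) " + inprod(Xa[k,], alpha)" else ""
  pri <- paste0("
  b0 ~ dnorm(0, pc)\n",
    if (nz) "  for (p in 1:Pz) { betaz[p] ~ dnorm(0, pc) }\n" else "",
    if (nr) "  for (p in 1:Pr) { betar[p] ~ dnorm(0, pc) }\n" else "",
    "  a0 ~ dnorm(0, pc)\n",
    if (na_) "  for (p in 1:Pa) { alpha[p] ~ dnorm(0, pc) }\n" else "")
  if (kind == "rilm") {
    return(paste0("model {
  prec <- exp(-a0)
  for (k in 1:K) {
    y[k] ~ dnorm(u0[s[k]]", rterm, ", prec)
  }
  for (i in 1:N) {
    mu0[i] <- b0", zterm, "
    u0[i] ~ dnorm(mu0[i], 1/(sv0*sv0))
    v0[i] <- u0[i] - mu0[i]
  }", pri, "
  sv0 ~ dt(0, ps, 1) T(0,)
}"))
  }
  if (kind == "mels") {
    return(paste0("model {
  for (k in 1:K) {
    lp[k] <- a0", aterm, " + v1[s[k]]
    y[k] ~ dnorm(u0[s[k]]", rterm, ", exp(-max(-30, min(30, lp[k]))))
  }
  for (i in 1:N) {
    mu0[i] <- b0", zterm, "
    u0[i] ~ dnorm(mu0[i], 1/(sv0*sv0))
    v0[i] <- u0[i] - mu0[i]
    v1[i] ~ dnorm(rho*sv1/sv0*v0[i], 1/((1-rho*rho)*sv1*sv1))
  }", pri, "
  sv0 ~ dt(0, ps, 1) T(0,)
  sv1 ~ dt(0, ps, 1) T(0,)
  rho ~ dunif(-1, 1)
}"))
  }
  paste0("model {
  for (k in 1:K) {
    lp[k] <- a0", aterm, " + eta1[s[k]] + d*lam[s[k]]
    y[k] ~ dnorm(u0[s[k]]", rterm, ", exp(-max(-30, min(30, lp[k]))))
  }
  for (r in 1:M) {
    m[r] ~ dbern(ilogit(t0 + inprod(Tm[r,], tau) + lam[sm[r]]))
  }
  for (i in 1:N) {
    mu0[i] <- b0", zterm, " + g*lam[i]
    u0[i] ~ dnorm(mu0[i], 1/(se0*se0))
    eta0[i] <- u0[i] - mu0[i]
    eta1[i] ~ dnorm(rho*se1/se0*eta0[i], 1/((1-rho*rho)*se1*se1))
    lam[i] ~ dnorm(0, 1/(sl*sl))
  }", pri, "
  t0 ~ dnorm(0, pc)
  for (q in 1:Q) { tau[q] ~ dnorm(0, pc) }
  g ~ dnorm(0, pc)
  d ~ dnorm(0, pc)
  se0 ~ dt(0, ps, 1) T(0,)
  se1 ~ dt(0, ps, 1) T(0,)
  sl ~ dt(0, ps, 1) T(0,)
  rho ~ dunif(-1, 1)
}")
}

# Split R-hat (each chain halved) for a draws matrix [iter x chain].
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  mns <- colMeans(sub)
  vrs <- apply(sub, 2, stats::var)
  W <- mean(vrs)
  B <- half * stats::var(mns)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Fit an imputation model by MCMC (Step 1)
#'
#' Draws from the posterior of the chosen model given the observed data,
#' with subject random effects sampled as latent quantities. RILM and MELS
#' use only rows with an observed outcome; SPMELS additionally models the
#' missingness indicator on every scheduled row.
#'
#' Non-convergence (any split R-hat above the configured threshold) is
#' flagged on the returned object with a warning, never silently accepted.
#'
#' @param kind `"rilm"`, `"mels"` or `"spmels"`.
#' @param data An `ema_dataset` (or validated data.frame).
#' @param outcome Outcome column name.
#' @param mean_covariates Columns of the mean submodel.
#' @param var_covariates Columns of the log WS-variance submodel
#'   (MELS/SPMELS; defaults to `mean_covariates`).
#' @param miss_covariates Columns of the missingness submodel (SPMELS).
#' @param config An [mcmc_config()].
#' @param seed Integer seed (drives the JAGS RNGs).
#' @return An object of class `posterior_draws`.
#' @export
fit_mcmc <- function(kind = c("rilm", "mels", "spmels"), data, outcome = "y",
                     mean_covariates, var_covariates = mean_covariates,
                     miss_covariates = c("day", "beep1", "beep6"),
                     config = mcmc_config(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(data), length(mean_covariates) >= 1)
  y <- data[[outcome]]
  obs <- which(!is.na(y))
  if (length(obs) == 0L) stop("no observed outcomes to fit")
  if (length(unique(data$subject[obs])) < 2)
    stop("need >= 2 subjects with observed outcomes")
  N <- n_subjects(data)
  X <- as.matrix(data[obs, mean_covariates, drop = FALSE])
  if (anyNA(X)) stop("missing mean covariates at observed-outcome rows")
  # subject-constant mean covariates enter the hierarchically centered
  # random-intercept mean (matrix Z, one row per subject)
  is_subj <- vapply(mean_covariates, function(cc)
    all(vapply(split(data[[cc]], data$subject), function(z) {
      z <- z[!is.na(z)]
      length(z) < 2 || diff(range(z)) < 1e-9
    }, logical(1))), logical(1))
  z_cols <- mean_covariates[is_subj]
  r_cols <- mean_covariates[!is_subj]
  jd <- list(K = length(obs), N = N, y = y[obs],
             s = data$subject[obs], pc = 1 / config$prior_coef_sd^2,
             ps = 1 / config$prior_scale_scale^2)
  if (length(z_cols)) {
    Z <- as.matrix(data[match(seq_len(N), data$subject), z_cols, drop = FALSE])
    jd$Z <- Z; jd$Pz <- ncol(Z)
  }
  if (length(r_cols)) {
    jd$Xr <- X[, r_cols, drop = FALSE]; jd$Pr <- length(r_cols)
  }
  monitors <- c("b0", if (length(z_cols)) "betaz",
                if (length(r_cols)) "betar", "a0")
  if (kind != "rilm") {
    Xa <- as.matrix(data[obs, var_covariates, drop = FALSE])
    if (anyNA(Xa)) stop("missing variance covariates at observed-outcome rows")
    if (ncol(Xa) > 0) { jd$Xa <- Xa; jd$Pa <- ncol(Xa) }
  }
  if (kind == "rilm") {
    monitors <- c(monitors, "sv0", "v0")
  } else if (kind == "mels") {
    monitors <- c(monitors, if (length(var_covariates)) "alpha",
                  "sv0", "sv1", "rho", "v0", "v1")
  } else {
    if (!all(data$m %in% c(0, 1)))
      stop("SPMELS requires m defined in {0,1} on all scheduled occasions")
    Tm <- as.matrix(data[, miss_covariates, drop = FALSE])
    if (anyNA(Tm)) stop("missing missingness covariates")
    jd$Tm <- Tm; jd$Q <- ncol(Tm); jd$M <- nrow(data)
    jd$m <- data$m; jd$sm <- data$subject
    monitors <- c(monitors, if (length(var_covariates)) "alpha",
                  "t0", "tau", "g", "d", "se0", "se1", "rho", "sl",
                  "eta0", "eta1", "lam")
  }
  code <- jags_code(kind, nz = length(z_cols), nr = length(r_cols),
                    na_ = if (kind == "rilm") 0L else length(var_covariates))
  inits <- lapply(seq_len(config$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.numeric(seed) * 97 + ch) %% 2147483587 + 1))
  jm <- rjags::jags.model(textConnection(code), data = jd, inits = inits,
                          n.chains = config$chains, n.adapt = config$adapt,
                          quiet = TRUE)
  if (config$burn > 0)
    stats::update(jm, config$burn, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitors, n.iter = config$iter,
                            thin = config$thin, progress.bar = "none")
  build_posterior_draws(kind, sm, outcome, mean_covariates, var_covariates,
                        miss_covariates, N, config,
                        z_cols = z_cols, r_cols = r_cols)
}

# Map JAGS node names to package parameter names.
rename_nodes <- function(kind, nodes, z_cols, r_cols, var_covariates,
                         miss_covariates) {
  out <- nodes
  out[nodes == "b0"] <- "beta0"
  out[nodes == "a0"] <- "alpha0"
  out[nodes == "sv0"] <- "sigma_v0"
  out[nodes == "sv1"] <- "sigma_v1"
  out[nodes == "se0"] <- "sigma_eta0"
  out[nodes == "se1"] <- "sigma_eta1"
  out[nodes == "sl"] <- "sigma_lambda"
  out[nodes == "g"] <- "gamma"
  out[nodes == "d"] <- "delta"
  out[nodes == "t0"] <- "tau0"
  out[nodes == "rho"] <- if (kind == "mels") "rho_v0v1" else "rho_eta0eta1"
  for (p in seq_along(z_cols))
    out[nodes == sprintf("betaz[%d]", p)] <- paste0("beta_", z_cols[p])
  if (length(z_cols) == 1L)
    out[nodes == "betaz"] <- paste0("beta_", z_cols[1])
  for (p in seq_along(r_cols))
    out[nodes == sprintf("betar[%d]", p)] <- paste0("beta_", r_cols[p])
  if (length(r_cols) == 1L)
    out[nodes == "betar"] <- paste0("beta_", r_cols[1])
  for (p in seq_along(var_covariates))
    out[nodes == sprintf("alpha[%d]", p)] <- paste0("alpha_", var_covariates[p])
  if (length(var_covariates) == 1L)
    out[nodes == "alpha"] <- paste0("alpha_", var_covariates[1])
  for (q in seq_along(miss_covariates))
    out[nodes == sprintf("tau[%d]", q)] <- paste0("tau_", miss_covariates[q])
  if (length(miss_covariates) == 1L)
    out[nodes == "tau"] <- paste0("tau_", miss_covariates[1])
  out
}

build_posterior_draws <- function(kind, sm, outcome, mean_covariates,
                                  var_covariates, miss_covariates, N, config,
                                  z_cols, r_cols) {
  nodes <- colnames(sm[[1]])
  effect_pat <- "^(v0|v1|eta0|eta1|lam)\\["
  is_eff <- grepl(effect_pat, nodes)
  all_mat <- do.call(rbind, lapply(sm, as.matrix))
  par_nodes <- nodes[!is_eff]
  pnames <- rename_nodes(kind, par_nodes, z_cols, r_cols, var_covariates,
                         miss_covariates)
  draws <- all_mat[, par_nodes, drop = FALSE]
  colnames(draws) <- pnames
  effects <- list()
  for (e in c("v0", "v1", "eta0", "eta1", "lam")) {
    cols <- paste0(e, "[", seq_len(N), "]")
    if (all(cols %in% nodes))
      effects[[e]] <- all_mat[, cols, drop = FALSE]
  }
  rhat <- vapply(par_nodes, function(nd)
    split_rhat(sapply(sm, function(ch) as.matrix(ch)[, nd])), numeric(1))
  ess <- tryCatch(
    vapply(par_nodes, function(nd)
      as.numeric(coda::effectiveSize(lapply(sm, function(ch) ch[, nd]))),
      numeric(1)),
    error = function(e) rep(NA_real_, length(par_nodes)))
  summ <- data.frame(
    parameter = pnames,
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = apply(draws, 2, stats::quantile, 0.025),
    q97.5 = apply(draws, 2, stats::quantile, 0.975),
    rhat = as.numeric(rhat),
    ess = as.numeric(ess),
    row.names = NULL)
  converged <- all(summ$rhat < config$rhat_threshold, na.rm = TRUE)
  if (!converged)
    warning(sprintf("MCMC not converged: max split R-hat = %.3f (%s)",
                    max(summ$rhat, na.rm = TRUE), kind))
  structure(list(kind = kind, outcome = outcome,
                 mean_covariates = mean_covariates,
                 var_covariates = if (kind == "rilm") character(0) else var_covariates,
                 miss_covariates = if (kind == "spmels") miss_covariates else character(0),
                 draws = draws, effects = effects, n_subjects = N,
                 n_chains = config$chains,
                 iter_per_chain = nrow(sm[[1]]),
                 summary = summ, converged = converged, config = config),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %s on '%s': %d draws (%d chains), %s\n",
              toupper(x$kind), x$outcome, nrow(x$draws), x$n_chains,
              if (x$converged) "converged" else
                sprintf("NOT converged (max R-hat %.3f)", max(x$summary$rhat))))
  print(cbind(round(x$summary[, c("mean", "sd", "q2.5", "q97.5", "rhat")], 3),
              parameter = x$summary$parameter))
  invisible(x)
}

# Reconstruct an ema_params object from draw row l of a posterior_draws fit.
params_from_draw <- function(fit, l) {
  d <- fit$draws[l, ]
  pick <- function(prefix, covs)
    stats::setNames(as.numeric(d[paste0(prefix, covs)]), covs)
  if (fit$kind == "rilm")
    return(rilm_params(beta0 = d[["beta0"]],
                       beta = pick("beta_", fit$mean_covariates),
                       alpha0 = d[["alpha0"]], sigma_v0 = d[["sigma_v0"]]))
  alpha <- if (length(fit$var_covariates))
    pick("alpha_", fit$var_covariates) else numeric(0)
  if (fit$kind == "mels")
    return(mels_params(beta0 = d[["beta0"]],
                       beta = pick("beta_", fit$mean_covariates),
                       alpha0 = d[["alpha0"]], alpha = alpha,
                       sigma_v0 = d[["sigma_v0"]], sigma_v1 = d[["sigma_v1"]],
                       rho_v0v1 = d[["rho_v0v1"]]))
  spmels_params(beta0 = d[["beta0"]],
                beta = pick("beta_", fit$mean_covariates),
                alpha0 = d[["alpha0"]], alpha = alpha,
                tau0 = d[["tau0"]], tau = pick("tau_", fit$miss_covariates),
                gamma = d[["gamma"]], delta = d[["delta"]],
                sigma_eta0 = d[["sigma_eta0"]], sigma_eta1 = d[["sigma_eta1"]],
                rho_eta0eta1 = d[["rho_eta0eta1"]],
                sigma_lambda = d[["sigma_lambda"]])
}

effects_from_draw <- function(fit, l) {
  g <- function(e) if (!is.null(fit$effects[[e]])) fit$effects[[e]][l, ] else NULL
  if (fit$kind == "spmels") {
    d <- fit$draws[l, ]
    subject_effects(eta0 = g("eta0"), eta1 = g("eta1"), lam = g("lam"),
                    gamma = d[["gamma"]], delta = d[["delta"]])
  } else {
    subject_effects(v0 = g("v0"), v1 = g("v1"))
  }
}

#' Fit the RILM by marginal maximum likelihood
#'
#' Direct maximization of the random-intercept model's marginal likelihood
#' (the subject covariance is compound-symmetric, so the per-subject
#' determinant and quadratic form have closed forms). Optimization is on the
#' unconstrained scale \eqn{(\beta_0, \beta, \alpha_0, \log\sigma_{v0})};
#' the observed-information covariance from the numerical Hessian on that
#' scale is what the ML-surrogate Step-1 draw uses, preserving positivity.
#' Empirical-Bayes conditional means and variances of the subject intercepts
#' are returned alongside.
#'
#' @param data An `ema_dataset` or data.frame with a `subject` column.
#' @param outcome Outcome column name.
#' @param mean_covariates Columns of the mean submodel.
#' @return An object of class `ml_fit` with `estimates` (natural scale),
#'   `phi`/`vcov_phi` (unconstrained scale), `summary` (with Wald 95%
#'   intervals), `eb` (subject-level conditional means/variances),
#'   `loglik`, and a `boundary` flag for a near-zero random-intercept SD.
#' @export
fit_rilm_ml <- function(data, outcome = "y", mean_covariates) {
  y <- data[[outcome]]
  obs <- which(!is.na(y))
  if (!length(obs)) stop("no observed outcomes to fit")
  X <- cbind(1, as.matrix(data[obs, mean_covariates, drop = FALSE]))
  if (anyNA(X)) stop("missing covariates at observed rows")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  yo <- y[obs]
  s <- data$subject[obs]
  N <- n_subjects(data)
  p <- ncol(X)

  nll <- function(phi) {
    beta <- phi[1:p]
    s2e <- exp(phi[p + 1])
    sv2 <- exp(2 * phi[p + 2])
    r <- yo - drop(X %*% beta)
    ssubj <- rowsum(cbind(r, r^2, 1), s)
    ni <- ssubj[, 3]
    rbar <- ssubj[, 1] / ni
    ssw <- ssubj[, 2] - ni * rbar^2
    denom <- s2e + ni * sv2
    0.5 * sum(ni * log(2 * pi) + (ni - 1) * log(s2e) + log(denom) +
                ssw / s2e + ni * rbar^2 / denom)
  }
  b_start <- stats::coef(stats::lm.fit(X, yo))
  r0 <- yo - drop(X %*% b_start)
  v_tot <- stats::var(r0)
  phi0 <- c(b_start, log(v_tot * 0.7), 0.5 * log(v_tot * 0.3 + 1e-6))
  opt <- stats::optim(phi0, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  phi <- opt$par
  V <- tryCatch(solve(opt$hessian), error = function(e) {
    ev <- eigen(opt$hessian, symmetric = TRUE)
    ev$vectors %*% diag(1 / pmax(ev$values, 1e-8)) %*% t(ev$vectors)
  })
  V <- (V + t(V)) / 2
  nm <- c("beta0", paste0("beta_", mean_covariates), "alpha0", "log_sigma_v0")
  names(phi) <- nm
  dimnames(V) <- list(nm, nm)
  est <- c(phi[1:(p + 1)], sigma_v0 = unname(exp(phi[p + 2])))
  boundary <- est[["sigma_v0"]] < 1e-3
  if (boundary)
    warning("estimated sigma_v0 is near zero (boundary)")

  # empirical-Bayes conditionals of v0 given phi-hat
  eb <- eb_rilm(phi, X, yo, s, N, p)
  se <- sqrt(diag(V))
  nat <- data.frame(parameter = c(nm[1:(p + 1)], "sigma_v0"),
                    estimate = as.numeric(est),
                    lower = c(phi[1:(p + 1)] - 1.96 * se[1:(p + 1)],
                              exp(phi[p + 2] - 1.96 * se[p + 2])),
                    upper = c(phi[1:(p + 1)] + 1.96 * se[1:(p + 1)],
                              exp(phi[p + 2] + 1.96 * se[p + 2])),
                    row.names = NULL)
  structure(list(kind = "rilm", outcome = outcome,
                 mean_covariates = mean_covariates,
                 estimates = est, phi = phi, vcov_phi = V,
                 summary = nat, eb = eb,
                 eb_fun = function(phi) eb_rilm(phi, X, yo, s, N, p),
                 loglik = -opt$value,
                 n_subjects = N, boundary = boundary,
                 converged = opt$convergence == 0),
            class = "ml_fit")
}

# Empirical-Bayes conditional mean/variance of v0 per subject under phi.
eb_rilm <- function(phi, X, yo, s, N, p) {
  beta <- phi[1:p]
  s2e <- exp(phi[p + 1])
  sv2 <- exp(2 * phi[p + 2])
  r <- yo - drop(X %*% beta)
  ssubj <- rowsum(cbind(r, 1), s)
  ni <- rep(0, N); rsum <- rep(0, N)
  idx <- as.integer(rownames(ssubj))
  ni[idx] <- ssubj[, 2]; rsum[idx] <- ssubj[, 1]
  denom <- s2e + ni * sv2
  data.frame(subject = seq_len(N),
             mean = sv2 * rsum / denom,
             var = sv2 * s2e / denom)
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("<ml_fit> RILM ML on '%s', logLik = %.2f%s\n", x$outcome,
              x$loglik, if (x$boundary) " [sigma_v0 at boundary]" else ""))
  print(cbind(round(x$summary[, c("estimate", "lower", "upper")], 3),
              parameter = x$summary$parameter))
  invisible(x)
}

#' Select Step-1 parameter/effect draws for imputation
#'
#' For an MCMC fit, returns `L` approximately independent retained draws,
#' selected by evenly spaced thinning across the concatenated chains, each
#' carrying its own subject-effect draw. For an ML fit, draws parameters
#' from the asymptotic normal \eqn{N(\hat\theta, \hat V)} on the
#' unconstrained scale and then subject intercepts from their
#' empirical-Bayes conditional distribution given that parameter draw.
#'
#' @param fit A `posterior_draws` or `ml_fit` object.
#' @param L Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A list of length `L` of `list(params = <ema_params>,
#'   effects = <subject_effects>)`, class `step1_draws`.
#' @export
draw_step1 <- function(fit, L, seed = 1L) UseMethod("draw_step1")

#' @export
draw_step1.posterior_draws <- function(fit, L, seed = 1L) {
  stopifnot(L >= 1)
  n <- nrow(fit$draws)
  if (L > n) stop(sprintf("L = %d exceeds %d retained draws", L, n))
  # evenly spaced over the concatenated chains; top up deterministically if
  # rounding collapsed neighbouring indices
  idx <- unique(round(seq(1, n, length.out = L)))
  if (length(idx) < L) {
    extra <- setdiff(seq_len(n), idx)
    idx <- sort(c(idx, extra[seq_len(L - length(idx))]))
  }
  out <- lapply(idx, function(l)
    list(params = params_from_draw(fit, l), effects = effects_from_draw(fit, l)))
  structure(out, class = "step1_draws", kind = fit$kind, outcome = fit$outcome)
}

#' @export
draw_step1.ml_fit <- function(fit, L, seed = 1L) {
  stopifnot(L >= 1)
  set.seed(as.integer(seed))
  p <- length(fit$mean_covariates) + 1L
  Phi <- MASS::mvrnorm(L, mu = fit$phi, Sigma = fit$vcov_phi)
  Phi <- matrix(Phi, nrow = L, dimnames = list(NULL, names(fit$phi)))
  out <- vector("list", L)
  yobs_cache <- NULL
  for (l in seq_len(L)) {
    phi <- Phi[l, ]
    params <- rilm_params(
      beta0 = phi[[1]],
      beta = stats::setNames(phi[seq_len(p - 1) + 1], fit$mean_covariates),
      alpha0 = phi[[p + 1]], sigma_v0 = exp(phi[[p + 2]]))
    eb <- fit$eb_fun(phi)
    v0 <- stats::rnorm(nrow(eb), eb$mean, sqrt(eb$var))
    out[[l]] <- list(params = params, effects = subject_effects(v0 = v0))
  }
  structure(out, class = "step1_draws", kind = "rilm", outcome = fit$outcome)
}

#' @export
print.step1_draws <- function(x, ...) {
  cat(sprintf("<step1_draws> %d %s draws for '%s'\n",
              length(x), toupper(attr(x, "kind")), attr(x, "outcome")))
  invisible(x)
}
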