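#' Within-subject variance at one occasion
#'
#' Evaluates the model's conditional (within-subject) variance
#' \eqn{\sigma^2_{\epsilon ij}}: a constant \eqn{e^{\alpha_0}} for RILM,
#' \eqn{e^{\alpha_0 + x'\alpha + v_1}} for MELS, and
#' \eqn{e^{\alpha_0 + x'\alpha + \eta_1 + \delta\lambda}} for SPMELS. The log
#' of the returned value is exactly the linear predictor, so the mapping is
#' invertible.
#'
#' @param params An `ema_params` object.
#' @param x_row Numeric covariate vector for the occasion, matched
#'   positionally against `params$alpha` (ignored for RILM; may be named).
#' @param effects_row For MELS a list/vector with `v1`; for SPMELS with
#'   `eta1` and `lam`; ignored for RILM.
#' @return Strictly positive scalar variance.
#' @examples
#' ws_variance(rilm_params(beta0 = 0, alpha0 = log(4), sigma_v0 = 1))
#' @export
ws_variance <- function(params, x_row = numeric(0), effects_row = list()) {
  exp(log_ws_variance(params, x_row, effects_row))
}

log_ws_variance <- function(params, x_row = numeric(0), effects_row = list()) {
  kind <- model_kind(params)
  if (kind == "rilm") return(params$alpha0)
  x_row <- as.numeric(x_row)
  if (length(x_row) != length(params$alpha))
    stop(sprintf("covariate row has length %d but alpha has length %d",
                 length(x_row), length(params$alpha)))
  lp <- params$alpha0 + sum(x_row * params$alpha)
  if (kind == "mels") lp + as.numeric(effects_row[["v1"]])
  else lp + as.numeric(effects_row[["eta1"]]) +
    params$delta * as.numeric(effects_row[["lam"]])
}

#' Missingness probability under the shared-parameter logistic submodel
#'
#' \eqn{P(m_{ij} = 1) = \mathrm{logit}^{-1}(\tau_0 + t_{ij}'\tau + \lambda_i)}.
#'
#' @param tau0 Intercept.
#' @param tau Coefficient vector (length q).
#' @param t_row Covariate vector for the occasion (length q).
#' @param lam_i Random missing effect of the subject.
#' @return Probability strictly inside (0, 1) for finite inputs.
#' @export
missingness_prob <- function(tau0, tau = numeric(0), t_row = numeric(0),
                             lam_i = 0) {
  if (length(t_row) != length(tau))
    stop(sprintf("missingness covariate row has length %d but tau has length %d",
                 length(t_row), length(tau)))
  stats::plogis(tau0 + sum(as.numeric(t_row) * tau) + lam_i)
}

# Design matrix for the coefficients named in `coefs`, taken from data columns.
# Unnamed coefficient vectors of length 0 yield a 0-column matrix.
coef_matrix <- function(data, coefs, what = "beta") {
  if (length(coefs) == 0L) return(matrix(0, nrow(data), 0))
  nms <- names(coefs)
  if (is.null(nms) || any(nms == ""))
    stop(sprintf("'%s' must be a named vector naming data columns", what))
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols))
    stop("data lacks covariate column(s): ", paste(missing_cols, collapse = ", "))
  as.matrix(data[, nms, drop = FALSE])
}

# Per-row conditional mean and log WS variance for all rows of `data`.
row_predictors <- function(params, data, effects) {
  i <- data$subject
  kind <- model_kind(params)
  Xb <- coef_matrix(data, params$beta, "beta")
  mu <- params$beta0 + (if (ncol(Xb)) drop(Xb %*% params$beta) else 0)
  mu <- rep_len(mu, nrow(data))
  lv <- switch(kind,
    rilm = {
      mu <- mu + effects$v0[i]
      rep(params$alpha0, nrow(data))
    },
    mels = {
      mu <- mu + effects$v0[i]
      Xa <- coef_matrix(data, params$alpha, "alpha")
      params$alpha0 + (if (ncol(Xa)) drop(Xa %*% params$alpha) else 0) +
        effects$v1[i]
    },
    spmels = {
      mu <- mu + effects$eta0[i] + params$gamma * effects$lam[i]
      Xa <- coef_matrix(data, params$alpha, "alpha")
      params$alpha0 + (if (ncol(Xa)) drop(Xa %*% params$alpha) else 0) +
        effects$eta1[i] + params$delta * effects$lam[i]
    })
  list(mu = mu, log_var = lv)
}

#' Outcome log-likelihood given subject effects
#'
#' Sum over the observed occasions of the normal log density with the
#' model's conditional mean and within-subject variance. Rows where the
#' outcome is `NA` do not contribute.
#'
#' @param params An `ema_params` object with named `beta` (and `alpha`)
#'   vectors naming columns of `data`.
#' @param data An EMA dataset (see [as_ema_dataset()]); must contain a
#'   `subject` column with integer codes 1..N.
#' @param effects A `subject_effects` object of length N.
#' @param outcome Name of the outcome column (default `"y"`).
#' @return Scalar log-likelihood.
#' @export
loglik_y <- function(params, data, effects, outcome = "y") {
  y <- data[[outcome]]
  keep <- !is.na(y)
  d <- data[keep, , drop = FALSE]
  cov_cols <- unique(c(names(params$beta), names(params$alpha)))
  for (cc in cov_cols)
    if (anyNA(d[[cc]]) || any(!is.finite(d[[cc]])))
      stop("non-finite covariate values in column ", cc, " at observed rows")
  if (any(!is.finite(y[keep]))) stop("non-finite outcome values")
  pr <- row_predictors(params, d, effects)
  sum(stats::dnorm(y[keep], mean = pr$mu, sd = exp(pr$log_var / 2), log = TRUE))
}

#' Missingness log-likelihood given subject effects (SPMELS)
#'
#' Sum of Bernoulli log-probabilities of the missingness indicator `m` over
#' all scheduled occasions — every row of `data` contributes exactly once,
#' whether the outcome is observed or missing.
#'
#' @param params An `spmels_params` object; `names(tau)` name columns of
#'   `data`.
#' @param data EMA dataset with an `m` column in \{0, 1\}.
#' @param effects `subject_effects` with `lam`.
#' @return Scalar log-likelihood.
#' @export
loglik_missing <- function(params, data, effects) {
  stopifnot(inherits(params, "spmels_params"))
  m <- data$m
  if (!all(m %in% c(0, 1))) stop("m must be 0/1 on every scheduled occasion")
  Tm <- coef_matrix(data, params$tau, "tau")
  eta <- params$tau0 + (if (ncol(Tm)) drop(Tm %*% params$tau) else 0) +
    effects$lam[data$subject]
  sum(ifelse(m == 1, stats::plogis(eta, log.p = TRUE),
             stats::plogis(-eta, log.p = TRUE)))
}

# Log density of the subject effects under the model's random-effect
# distribution: univariate normal (RILM), bivariate normal via the
# conditional factorization (MELS; robust to a vanishing scale-effect SD),
# or the block-diagonal trivariate normal of SPMELS.
loglik_effects <- function(params, effects) {
  bvn <- function(a, b, s0, s1, r)
    sum(stats::dnorm(a, 0, s0, log = TRUE) +
          stats::dnorm(b, r * s1 / s0 * a, s1 * sqrt(1 - r^2), log = TRUE))
  switch(model_kind(params),
    rilm = sum(stats::dnorm(effects$v0, 0, params$sigma_v0, log = TRUE)),
    mels = bvn(effects$v0, effects$v1, params$sigma_v0, params$sigma_v1,
               params$rho_v0v1),
    spmels = bvn(effects$eta0, effects$eta1, params$sigma_eta0,
                 params$sigma_eta1, params$rho_eta0eta1) +
      sum(stats::dnorm(effects$lam, 0, params$sigma_lambda, log = TRUE)))
}

#' Unnormalized joint log density of data and subject effects
#'
#' The conditional-on-effects joint used by the sampler:
#' outcome log-likelihood + (SPMELS) missingness log-likelihood + log density
#' of the subject effects under their random-effect distribution.
#'
#' @inheritParams loglik_y
#' @return Scalar log density.
#' @export
joint_log_density <- function(params, data, effects, outcome = "y") {
  ll <- loglik_y(params, data, effects, outcome = outcome) +
    loglik_effects(params, effects)
  if (model_kind(params) == "spmels")
    ll <- ll + loglik_missing(params, data, effects)
  ll
}

#' Share of random-effect variance attributable to missingness
#'
#' Under the shared-parameter decomposition \eqn{v = \gamma\lambda + \eta},
#' the fraction of the variance of \eqn{v} explained by the random missing
#' effect is
#' \deqn{\frac{(\gamma\sigma_\lambda)^2}{(\gamma\sigma_\lambda)^2 + \sigma_\eta^2}.}
#'
#' @param loading Loading of the missing effect (\eqn{\gamma} or \eqn{\delta}).
#' @param sigma_lambda SD of the random missing effect, > 0.
#' @param sigma_resid SD of the residual effect (\eqn{\sigma_{\eta_0}} or
#'   \eqn{\sigma_{\eta_1}}), >= 0.
#' @return Proportion in \[0, 1\] (multiply by 100 for a percentage).
#' @examples
#' 100 * variance_share(-0.46, 1.39, 1.66)
#' @export
variance_share <- function(loading, sigma_lambda, sigma_resid) {
  stopifnot(sigma_lambda > 0, sigma_resid >= 0)
  a <- (loading * sigma_lambda)^2
  if (a == 0 && sigma_resid == 0) stop("share undefined: both terms zero")
  a / (a + sigma_resid^2)
}
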