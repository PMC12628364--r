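#' Parameter containers for the three imputation models
#'
#' Constructors for the parameter sets of the random-intercept linear mixed
#' model (RILM), the mixed-effects location-scale model (MELS), and the
#' shared-parameter MELS (SPMELS). All three share a mean submodel
#' \eqn{E[y_{ij}] = \beta_0 + x_{ij}'\beta + v_{0,i}}; they differ in the
#' within-subject (WS) variance submodel and in whether missingness is
#' modelled jointly with the outcome.
#'
#' The WS variance is always held on the log scale: for RILM it is the
#' constant \eqn{e^{\alpha_0}}; for MELS
#' \eqn{\sigma^2_{\epsilon ij} = e^{\alpha_0 + x_{ij}'\alpha + v_{1,i}}};
#' for SPMELS
#' \eqn{e^{\alpha_0 + x_{ij}'\alpha + \eta_{1,i} + \delta\lambda_i}}.
#' SPMELS decomposes the random location and scale effects as
#' \eqn{v_{0,i} = \gamma\lambda_i + \eta_{0,i}} and
#' \eqn{v_{1,i} = \delta\lambda_i + \eta_{1,i}}, where \eqn{\lambda_i} is the
#' random missing effect of a logistic submodel for the missingness
#' indicator, independent of \eqn{(\eta_{0,i},\eta_{1,i})}.
#'
#' Random-effect covariances are parameterised as (SD, SD, correlation), so
#' the positive-definiteness invariants are directly checkable.
#'
#' @param beta0 Mean-model intercept.
#' @param beta Named or unnamed numeric vector of mean-model coefficients
#'   (length p; may be length 0).
#' @param alpha0 Intercept of the log WS-variance submodel. For RILM this is
#'   the log of the constant WS variance.
#' @param alpha Numeric vector of WS-variance coefficients (MELS/SPMELS).
#' @param sigma_v0 SD of the random location effect (RILM/MELS), > 0.
#' @param sigma_v1 SD of the random scale effect (MELS), > 0.
#' @param rho_v0v1 Correlation between location and scale effects, in (-1, 1).
#' @param tau0 Missingness-model intercept (SPMELS).
#' @param tau Numeric vector of missingness-model coefficients (length q).
#' @param gamma Loading of the random missing effect on the location.
#' @param delta Loading of the random missing effect on the log WS variance.
#' @param sigma_eta0,sigma_eta1 SDs of the residual random location/scale
#'   effects (SPMELS), > 0.
#' @param rho_eta0eta1 Correlation of the residual effects, in (-1, 1).
#' @param sigma_lambda SD of the random missing effect, > 0.
#'
#' @return An object of class `rilm_params`, `mels_params` or
#'   `spmels_params` (all also `ema_params`).
#' @examples
#' p <- mels_params(beta0 = 1, beta = c(x1 = 0.5), alpha0 = 0,
#'                  alpha = c(x1 = 0.3), sigma_v0 = 1, sigma_v1 = 0.5,
#'                  rho_v0v1 = -0.2)
#' model_kind(p)
#' @name ema_params
NULL

#' @rdname ema_params
#' @export
rilm_params <- function(beta0, beta = numeric(0), alpha0, sigma_v0) {
  obj <- structure(
    list(beta0 = beta0, beta = beta, alpha0 = alpha0, sigma_v0 = sigma_v0),
    class = c("rilm_params", "ema_params"))
  validate_params(obj)
}

#' @rdname ema_params
#' @export
mels_params <- function(beta0, beta = numeric(0), alpha0, alpha = numeric(0),
                        sigma_v0, sigma_v1, rho_v0v1 = 0) {
  obj <- structure(
    list(beta0 = beta0, beta = beta, alpha0 = alpha0, alpha = alpha,
         sigma_v0 = sigma_v0, sigma_v1 = sigma_v1, rho_v0v1 = rho_v0v1),
    class = c("mels_params", "ema_params"))
  validate_params(obj)
}

#' @rdname ema_params
#' @export
spmels_params <- function(beta0, beta = numeric(0), alpha0, alpha = numeric(0),
                          tau0, tau = numeric(0), gamma, delta,
                          sigma_eta0, sigma_eta1, rho_eta0eta1 = 0,
                          sigma_lambda) {
  obj <- structure(
    list(beta0 = beta0, beta = beta, alpha0 = alpha0, alpha = alpha,
         tau0 = tau0, tau = tau, gamma = gamma, delta = delta,
         sigma_eta0 = sigma_eta0, sigma_eta1 = sigma_eta1,
         rho_eta0eta1 = rho_eta0eta1, sigma_lambda = sigma_lambda),
    class = c("spmels_params", "ema_params"))
  validate_params(obj)
}

#' Model kind of a parameter set
#'
#' @param params An `ema_params` object.
#' @return One of `"rilm"`, `"mels"`, `"spmels"`.
#' @export
model_kind <- function(params) {
  stopifnot(inherits(params, "ema_params"))
  sub("_params$", "", class(params)[1L])
}

#' Validate a parameter container
#'
#' Checks the invariants of each model's parameter set: positive SDs,
#' correlations strictly inside (-1, 1), finite values, and (SPMELS) a
#' positive-definite block-diagonal covariance of
#' \eqn{(\eta_0, \eta_1, \lambda)}.
#'
#' @param params An `ema_params` object.
#' @return `params`, invisibly usable; errors on violation.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "ema_params"))
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  with(params, {
    if (!num_ok(beta0) || !num_ok(beta) || !num_ok(alpha0))
      stop("non-finite value in mean/variance coefficients")
  })
  kind <- model_kind(params)
  if (kind == "rilm") {
    if (!(params$sigma_v0 > 0)) stop("sigma_v0 must be > 0")
  } else if (kind == "mels") {
    if (!(params$sigma_v0 > 0)) stop("sigma_v0 must be > 0")
    if (!(params$sigma_v1 > 0)) stop("sigma_v1 must be > 0")
    if (!(abs(params$rho_v0v1) < 1)) stop("|rho_v0v1| must be < 1")
  } else {
    if (!(params$sigma_eta0 > 0)) stop("sigma_eta0 must be > 0")
    if (!(params$sigma_eta1 > 0)) stop("sigma_eta1 must be > 0")
    if (!(params$sigma_lambda > 0)) stop("sigma_lambda must be > 0")
    if (!(abs(params$rho_eta0eta1) < 1)) stop("|rho_eta0eta1| must be < 1")
    if (!is.numeric(params$tau0) || !all(is.finite(c(params$tau0, params$tau))))
      stop("non-finite missingness coefficients")
    # block-diagonal 3x3 covariance must be PD; with SDs > 0 and |rho| < 1
    # this reduces to the 2x2 eta block being PD, asserted here explicitly
    S <- effects_covariance(params)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("random-effect covariance is not positive definite")
  }
  params
}

#' Random-effect covariance matrix implied by a parameter set
#'
#' For MELS, the 2x2 covariance of \eqn{(v_0, v_1)}; for SPMELS, the 3x3
#' block-diagonal covariance of \eqn{(\eta_0, \eta_1, \lambda)}; for RILM,
#' the 1x1 matrix \eqn{\sigma_{v0}^2}.
#'
#' @param params An `ema_params` object.
#' @return A symmetric positive-definite matrix.
#' @export
effects_covariance <- function(params) {
  switch(model_kind(params),
    rilm = matrix(params$sigma_v0^2, 1, 1, dimnames = list("v0", "v0")),
    mels = {
      s <- c(params$sigma_v0, params$sigma_v1)
      S <- diag(s^2)
      S[1, 2] <- S[2, 1] <- params$rho_v0v1 * s[1] * s[2]
      dimnames(S) <- list(c("v0", "v1"), c("v0", "v1"))
      S
    },
    spmels = {
      s <- c(params$sigma_eta0, params$sigma_eta1)
      S <- diag(c(s^2, params$sigma_lambda^2))
      S[1, 2] <- S[2, 1] <- params$rho_eta0eta1 * s[1] * s[2]
      nm <- c("eta0", "eta1", "lambda")
      dimnames(S) <- list(nm, nm)
      S
    })
}

#' Subject-level random effects
#'
#' Container for per-subject random effects. For RILM only `v0` is used; for
#' MELS `v0` and `v1`; for SPMELS the primitive effects are `eta0`, `eta1`
#' and `lam`, from which the composite location/scale effects
#' `v0 = gamma*lam + eta0` and `v1 = delta*lam + eta1` are derived when the
#' loadings are supplied.
#'
#' @param v0 Numeric vector of random location effects (length N), or NULL
#'   to derive from `eta0`/`lam` (SPMELS).
#' @param v1 Random scale effects, or NULL.
#' @param lam Random missing effects (SPMELS).
#' @param eta0,eta1 Residual random location/scale effects (SPMELS).
#' @param gamma,delta Loadings used to derive `v0`, `v1` when eta/lam given.
#' @return An object of class `subject_effects`.
#' @export
subject_effects <- function(v0 = NULL, v1 = NULL, lam = NULL,
                            eta0 = NULL, eta1 = NULL,
                            gamma = NULL, delta = NULL) {
  if (is.null(v0) && !is.null(eta0)) {
    stopifnot(!is.null(lam), !is.null(gamma))
    v0 <- gamma * lam + eta0
  }
  if (is.null(v1) && !is.null(eta1)) {
    stopifnot(!is.null(lam), !is.null(delta))
    v1 <- delta * lam + eta1
  }
  stopifnot(is.numeric(v0))
  n <- length(v0)
  for (x in list(v1, lam, eta0, eta1))
    if (!is.null(x)) stopifnot(length(x) == n)
  structure(list(v0 = v0, v1 = v1, lam = lam, eta0 = eta0, eta1 = eta1),
            class = "subject_effects")
}

#' Draw subject effects from their distribution under a parameter set
#'
#' @param params An `ema_params` object.
#' @param n Number of subjects.
#' @return A `subject_effects` object with `n` rows of effects.
#' @export
draw_subject_effects <- function(params, n) {
  S <- effects_covariance(params)
  Z <- MASS::mvrnorm(n, mu = rep(0, nrow(S)), Sigma = S)
  Z <- matrix(Z, nrow = n)
  switch(model_kind(params),
    rilm = subject_effects(v0 = Z[, 1]),
    mels = subject_effects(v0 = Z[, 1], v1 = Z[, 2]),
    spmels = subject_effects(eta0 = Z[, 1], eta1 = Z[, 2], lam = Z[, 3],
                             gamma = params$gamma, delta = params$delta))
}

#' @export
print.ema_params <- function(x, ...) {
  cat(sprintf("<%s> %s model parameters\n", class(x)[1], toupper(model_kind(x))))
  flat <- unlist(x)
  print(round(flat, 4))
  invisible(x)
}

#' @export
print.subject_effects <- function(x, ...) {
  used <- names(x)[!vapply(x, is.null, logical(1))]
  cat(sprintf("<subject_effects> N = %d, components: %s\n",
              length(x$v0), paste(used, collapse = ", ")))
  invisible(x)
}
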