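#' Simulation scenario for synthetic EMA data
#'
#' Defines the generative process for an EMA study with informative
#' missingness. Subjects are scheduled for `n_days` days with `n_beeps`
#' prompts per day. A time-constant covariate `x2` is drawn per subject; a
#' random missing effect \eqn{\lambda_i} drives a logistic missingness model
#' with a day trend and first/last-beep effects; the time-varying covariate
#' `x1` and the outcome `y` are each generated from a shared-parameter
#' location-scale block that loads on the same \eqn{\lambda_i}. Where the
#' missingness indicator is 1, `x1` and `y` are masked together.
#'
#' The missingness intercept \eqn{\tau_0} is not a free setting: it is
#' calibrated per scenario by [calibrate_tau0()] so the expected missing
#' fraction equals `target_missing_rate`.
#'
#' Scenario knobs mirror the quantities varied in the package's simulation
#' study: `alpha0_y` (WS-variance intercept of the outcome block),
#' `rho_y` (residual location-scale correlation), and the outcome block's
#' missingness loadings `gamma_y`, `delta_y`.
#'
#' @param n_subjects,n_days,n_beeps Design size (defaults 20, 5, 6).
#' @param mu_x2,sigma_x2 Mean and SD of the time-constant covariate.
#' @param tau Named vector of missingness coefficients for columns
#'   `day`, `beep1`, `beep6`.
#' @param sigma_lambda SD of the random missing effect.
#' @param x1_params Parameter block (list) for the `x1` generating model:
#'   `beta0`, `beta` (named, over `x2`), `alpha0`, `alpha` (named),
#'   `gamma`, `delta`, `sigma_eta0`, `sigma_eta1`, `rho`.
#' @param y_params Same structure for the outcome block (`beta`/`alpha`
#'   named over `x1`, `x2`).
#' @param alpha0_y,rho_y,gamma_y,delta_y Convenience overrides applied to
#'   `y_params` (the scenario-grid knobs).
#' @param target_missing_rate Design missing fraction in (0, 1).
#' @param seed Default seed for [generate_dataset()].
#' @return An object of class `ema_scenario`.
#' @examples
#' sc <- ema_scenario()
#' sc$y_params$alpha0
#' @export
ema_scenario <- function(n_subjects = 20, n_days = 5, n_beeps = 6,
                         mu_x2 = 0, sigma_x2 = 1,
                         tau = c(day = 0.2, beep1 = 0.5, beep6 = 0.5),
                         sigma_lambda = 1,
                         x1_params = list(
                           beta0 = 0, beta = c(x2 = 0.5),
                           alpha0 = 0, alpha = c(x2 = 0.3),
                           gamma = -0.5, delta = 0.5,
                           sigma_eta0 = 1, sigma_eta1 = 0.5, rho = -0.2),
                         y_params = list(
                           beta0 = 1, beta = c(x1 = 0.5, x2 = 0.5),
                           alpha0 = 0, alpha = c(x1 = 0.3, x2 = 0.3),
                           gamma = -0.5, delta = 0.5,
                           sigma_eta0 = 1, sigma_eta1 = 0.5, rho = -0.2),
                         alpha0_y = NULL, rho_y = NULL,
                         gamma_y = NULL, delta_y = NULL,
                         target_missing_rate = 0.2, seed = 1L) {
  if (!is.null(alpha0_y)) y_params$alpha0 <- alpha0_y
  if (!is.null(rho_y)) y_params$rho <- rho_y
  if (!is.null(gamma_y)) y_params$gamma <- gamma_y
  if (!is.null(delta_y)) y_params$delta <- delta_y
  stopifnot(n_subjects >= 1, n_days >= 1, n_beeps >= 1,
            target_missing_rate > 0, target_missing_rate < 1,
            sigma_lambda >= 0, sigma_x2 > 0)
  for (blk in list(x1_params, y_params))
    stopifnot(blk$sigma_eta0 > 0, blk$sigma_eta1 > 0, abs(blk$rho) < 1)
  structure(list(n_subjects = n_subjects, n_days = n_days, n_beeps = n_beeps,
                 mu_x2 = mu_x2, sigma_x2 = sigma_x2, tau = tau,
                 sigma_lambda = sigma_lambda, x1_params = x1_params,
                 y_params = y_params,
                 target_missing_rate = target_missing_rate, seed = seed),
            class = "ema_scenario")
}

# Scheduled design rows (no data yet): subject x day x beep with indicators.
schedule_design <- function(scenario) {
  g <- expand.grid(beep = seq_len(scenario$n_beeps),
                   day = seq_len(scenario$n_days),
                   subject = seq_len(scenario$n_subjects))
  g <- g[, c("subject", "day", "beep")]
  g$beep1 <- as.integer(g$beep == 1)
  g$beep6 <- as.integer(g$beep == scenario$n_beeps)
  g
}

#' Calibrate the missingness intercept to the target missing rate
#'
#' Solves for \eqn{\tau_0} such that the missing fraction expected under the
#' scenario — averaged over the scheduled day/beep design and over the
#' \eqn{\lambda \sim N(0, \sigma_\lambda^2)} distribution (Gauss–Hermite
#' quadrature) — equals `target_missing_rate`. The expected rate is strictly
#' increasing in \eqn{\tau_0}, so monotone root-finding applies; the root is
#' located to 1e-6 in `tau0` (giving a much tighter rate error).
#'
#' Calibration is per scenario, not per generated replicate, so \eqn{\tau_0}
#' is a deterministic function of the design and a well-defined estimand.
#'
#' @param scenario An `ema_scenario`.
#' @param gh_nodes Number of Gauss–Hermite nodes (default 40).
#' @return The calibrated scalar \eqn{\tau_0}.
#' @export
calibrate_tau0 <- function(scenario, gh_nodes = 40) {
  des <- schedule_design(scenario)
  des <- des[des$subject == 1L, c("day", "beep1", "beep6")]
  lp0 <- drop(as.matrix(des) %*% scenario$tau[c("day", "beep1", "beep6")])
  if (scenario$sigma_lambda > 0) {
    gh <- pracma::gaussHermite(gh_nodes)
    lam <- sqrt(2) * scenario$sigma_lambda * gh$x
    w <- gh$w / sqrt(pi)
    expected_rate <- function(tau0)
      mean(colSums(w * stats::plogis(outer(lam, tau0 + lp0, `+`))))
  } else {
    expected_rate <- function(tau0) mean(stats::plogis(tau0 + lp0))
  }
  f <- function(tau0) expected_rate(tau0) - scenario$target_missing_rate
  sol <- stats::uniroot(f, lower = -50, upper = 50, tol = 1e-10)
  root <- sol$root
  stopifnot(abs(f(root)) < 1e-6)
  root
}

# Draw a bivariate-normal effects matrix with SDs (s0, s1) and correlation r.
rbvn <- function(n, s0, s1, r) {
  z0 <- stats::rnorm(n)
  z1 <- r * z0 + sqrt(1 - r^2) * stats::rnorm(n)
  cbind(s0 * z0, s1 * z1)
}

#' Generate a synthetic EMA dataset with informative missingness
#'
#' Runs the scenario's four-step generative process: (1) draw the
#' time-constant covariate `x2`; (2) draw the random missing effects
#' \eqn{\lambda_i} and the missingness indicators from the logistic
#' submodel with the calibrated intercept; (3) draw `x1` from its
#' shared-parameter location-scale block given `x2` and \eqn{\lambda_i};
#' (4) draw `y` from its block given `x1`, `x2` and \eqn{\lambda_i}. Where
#' `m = 1`, `x1` and `y` are masked together; their pre-masking values are
#' kept in `true_x1`, `true_y`.
#'
#' The result carries the calibrated `tau0` and the per-subject true effects
#' of both blocks as attributes (for recovery and error computations).
#'
#' @param scenario An `ema_scenario`.
#' @param seed Integer seed (defaults to `scenario$seed`).
#' @param tau0 Optional pre-calibrated intercept; calibrated when NULL.
#' @return An `ema_dataset` with `true_*` columns and attributes
#'   `tau0`, `true_effects` (list with `lam`, `x1`, `y` components).
#' @export
generate_dataset <- function(scenario, seed = scenario$seed, tau0 = NULL) {
  stopifnot(inherits(scenario, "ema_scenario"))
  if (is.null(tau0)) tau0 <- calibrate_tau0(scenario)
  set.seed(seed)
  N <- scenario$n_subjects
  d <- schedule_design(scenario)
  i <- d$subject

  # step 1: time-constant covariate
  x2_i <- stats::rnorm(N, scenario$mu_x2, scenario$sigma_x2)
  d$x2 <- x2_i[i]

  # step 2: random missing effect and missingness indicator
  lam <- stats::rnorm(N, 0, scenario$sigma_lambda)
  lp_m <- tau0 + drop(as.matrix(d[, c("day", "beep1", "beep6")]) %*%
                        scenario$tau[c("day", "beep1", "beep6")]) + lam[i]
  d$m <- stats::rbinom(nrow(d), 1, stats::plogis(lp_m))

  # step 3: time-varying covariate block
  p1 <- scenario$x1_params
  e1 <- rbvn(N, p1$sigma_eta0, p1$sigma_eta1, p1$rho)
  mu1 <- p1$beta0 + p1$beta[["x2"]] * d$x2 + e1[i, 1] + p1$gamma * lam[i]
  lv1 <- p1$alpha0 + p1$alpha[["x2"]] * d$x2 + e1[i, 2] + p1$delta * lam[i]
  x1 <- stats::rnorm(nrow(d), mu1, exp(lv1 / 2))

  # step 4: outcome block
  p2 <- scenario$y_params
  e2 <- rbvn(N, p2$sigma_eta0, p2$sigma_eta1, p2$rho)
  mu2 <- p2$beta0 + p2$beta[["x1"]] * x1 + p2$beta[["x2"]] * d$x2 +
    e2[i, 1] + p2$gamma * lam[i]
  lv2 <- p2$alpha0 + p2$alpha[["x1"]] * x1 + p2$alpha[["x2"]] * d$x2 +
    e2[i, 2] + p2$delta * lam[i]
  y <- stats::rnorm(nrow(d), mu2, exp(lv2 / 2))

  d$true_x1 <- x1
  d$true_y <- y
  d$x1 <- ifelse(d$m == 1, NA_real_, x1)
  d$y <- ifelse(d$m == 1, NA_real_, y)
  d <- d[, c("subject", "day", "beep", "beep1", "beep6",
             "x2", "x1", "y", "m", "true_x1", "true_y")]
  out <- as_ema_dataset(d)
  attr(out, "tau0") <- tau0
  attr(out, "true_effects") <- list(
    lam = lam,
    x1 = subject_effects(eta0 = e1[, 1], eta1 = e1[, 2], lam = lam,
                         gamma = p1$gamma, delta = p1$delta),
    y = subject_effects(eta0 = e2[, 1], eta1 = e2[, 2], lam = lam,
                        gamma = p2$gamma, delta = p2$delta))
  attr(out, "scenario") <- scenario
  out
}

#' True parameter values implied by a scenario for each fitted model
#'
#' Maps the generating outcome block to the estimands of each fitted model
#' kind. MELS (and RILM) estimate the composite effects
#' \eqn{v_0 = \gamma\lambda + \eta_0}, \eqn{v_1 = \delta\lambda + \eta_1},
#' so their true SDs and correlation are derived from the block:
#' \eqn{\sigma_{v0} = \sqrt{\gamma^2\sigma_\lambda^2 + \sigma_{\eta_0}^2}}
#' etc. Coefficients of covariates absent from the generating model (day and
#' beep indicators in the imputation models) have true value 0.
#'
#' @param scenario An `ema_scenario`.
#' @param kind `"rilm"`, `"mels"` or `"spmels"`.
#' @param block `"y"` (default) or `"x1"`.
#' @return Named numeric vector of true values.
#' @export
true_values <- function(scenario, kind = c("rilm", "mels", "spmels"),
                        block = c("y", "x1")) {
  kind <- match.arg(kind)
  block <- match.arg(block)
  p <- if (block == "y") scenario$y_params else scenario$x1_params
  sl <- scenario$sigma_lambda
  sv0 <- sqrt(p$gamma^2 * sl^2 + p$sigma_eta0^2)
  sv1 <- sqrt(p$delta^2 * sl^2 + p$sigma_eta1^2)
  rho_v <- (p$gamma * p$delta * sl^2 + p$rho * p$sigma_eta0 * p$sigma_eta1) /
    (sv0 * sv1)
  base <- c(beta0 = p$beta0,
            stats::setNames(as.numeric(p$beta), paste0("beta_", names(p$beta))),
            alpha0 = p$alpha0)
  switch(kind,
    rilm = c(base, sigma_v0 = sv0),
    mels = c(base,
             stats::setNames(as.numeric(p$alpha), paste0("alpha_", names(p$alpha))),
             sigma_v0 = sv0, sigma_v1 = sv1, rho_v0v1 = rho_v),
    spmels = c(base,
               stats::setNames(as.numeric(p$alpha), paste0("alpha_", names(p$alpha))),
               gamma = p$gamma, delta = p$delta,
               sigma_eta0 = p$sigma_eta0, sigma_eta1 = p$sigma_eta1,
               rho_eta0eta1 = p$rho, sigma_lambda = sl))
}

#' @export
print.ema_scenario <- function(x, ...) {
  cat(sprintf(paste0("<ema_scenario> %d subjects x %d days x %d beeps, ",
                     "target missing %.0f%%\n"),
              x$n_subjects, x$n_days, x$n_beeps, 100 * x$target_missing_rate))
  cat(sprintf("  y block: alpha0 = %.2f, rho = %.2f, gamma = %.2f, delta = %.2f\n",
              x$y_params$alpha0, x$y_params$rho,
              x$y_params$gamma, x$y_params$delta))
  invisible(x)
}

#' Read / write a scenario as JSON
#'
#' @param scenario An `ema_scenario`.
#' @param path File path.
#' @return `read_scenario()` returns an `ema_scenario`; `write_scenario()`
#'   the path, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  # named vectors serialize as JSON objects so the names survive round-trip
  x$tau <- as.list(x$tau)
  for (blk in c("x1_params", "y_params"))
    for (f in c("beta", "alpha"))
      x[[blk]][[f]] <- as.list(x[[blk]][[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (blk in c("x1_params", "y_params"))
    for (f in c("beta", "alpha"))
      raw[[blk]][[f]] <- unlist(raw[[blk]][[f]])
  raw$tau <- unlist(raw$tau)
  do.call(ema_scenario, raw)
}
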