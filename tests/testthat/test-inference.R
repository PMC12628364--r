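make_rilm_data <- function(N, n_per, beta0 = 1, b1 = 0.5, s_eps = 1,
                           s_v0 = 0.8, seed = 1) {
  set.seed(seed)
  d <- data.frame(subject = rep(seq_len(N), each = n_per),
                  day = rep(seq_len(n_per), N), beep = 1L,
                  beep1 = 1L, beep6 = 0L,
                  x2 = rep(rnorm(N), each = n_per),
                  x1 = rnorm(N * n_per))
  v0 <- rnorm(N, 0, s_v0)
  d$y <- beta0 + b1 * d$x1 + v0[d$subject] + rnorm(N * n_per, 0, s_eps)
  d$m <- 0L
  as_ema_dataset(d)
}

test_that("RILM marginal ML agrees with lme4 on a common dataset", {
  skip_if_not_installed("lme4")
  d <- make_rilm_data(40, 8, seed = 2)
  fit <- fit_rilm_ml(d, outcome = "y", mean_covariates = c("x1", "x2"))
  lf <- lme4::lmer(y ~ x1 + x2 + (1 | subject), data = d, REML = FALSE)
  expect_equal(unname(fit$estimates[c("beta0", "beta_x1", "beta_x2")]),
               unname(lme4::fixef(lf)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(exp(fit$estimates[["alpha0"]]),
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
  expect_equal(fit$estimates[["sigma_v0"]]^2,
               vc$vcov[vc$grp == "subject"], tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-5)
  # empirical-Bayes means match lme4's conditional modes
  expect_equal(fit$eb$mean, lme4::ranef(lf)$subject[, 1], tolerance = 1e-3)
})

test_that("RILM ML collapses to OLS without between-subject variance", {
  # residuals centered within subject force the variance-component estimate
  # to the boundary, where GLS and OLS coincide
  d <- make_rilm_data(30, 10, s_v0 = 0, s_eps = 0, seed = 3)
  set.seed(3)
  e <- rnorm(nrow(d))
  d$y <- d$y + e - ave(e, d$subject)
  fit <- suppressWarnings(
    fit_rilm_ml(d, outcome = "y", mean_covariates = c("x1", "x2")))
  expect_true(fit$boundary)
  ols <- coef(lm(y ~ x1 + x2, data = d))
  expect_equal(unname(fit$estimates[1:3]), unname(ols), tolerance = 1e-6)
})

test_that("RILM ML recovers parameters and the pooled-variance moment", {
  d <- make_rilm_data(200, 30, beta0 = 1, b1 = 0.5, s_eps = 1.2, s_v0 = 0.8,
                      seed = 4)
  fit <- fit_rilm_ml(d, outcome = "y", mean_covariates = c("x1", "x2"))
  se <- sqrt(diag(fit$vcov_phi))
  expect_lt(abs(fit$estimates[["beta0"]] - 1), 3 * se[1])
  expect_lt(abs(fit$estimates[["beta_x1"]] - 0.5), 3 * se[2])
  expect_lt(abs(fit$estimates[["alpha0"]] - log(1.2^2)), 3 * se[4])
  expect_lt(abs(fit$phi[["log_sigma_v0"]] - log(0.8)), 3 * se[5])
  # alpha0-hat is approximately the log pooled within-subject residual variance
  r <- d$y - ave(d$y, d$subject)
  xr <- d$x1 - ave(d$x1, d$subject)
  pooled <- sum((r - coef(lm(r ~ xr + 0)) * xr)^2) / (nrow(d) - 200)
  expect_equal(fit$estimates[["alpha0"]], log(pooled), tolerance = 0.02)
})

test_that("ML-path Step-1 draws have the asymptotic-normal behavior", {
  d <- make_rilm_data(25, 8, seed = 5)
  fit <- fit_rilm_ml(d, outcome = "y", mean_covariates = c("x1", "x2"))
  # degenerate covariance: all draws equal the estimate
  fit0 <- fit
  fit0$vcov_phi[] <- 0
  dr <- draw_step1(fit0, 5, seed = 1)
  expect_length(dr, 5)
  for (l in 1:5)
    expect_equal(dr[[l]]$params$beta0, fit$phi[["beta0"]], tolerance = 1e-12)
  # single draw is a valid (params, effects) pair
  d1 <- draw_step1(fit, 1, seed = 2)
  expect_s3_class(d1[[1]]$params, "rilm_params")
  expect_length(d1[[1]]$effects$v0, 25)
  # draw mean over many draws recovers the estimate within MC error
  drL <- draw_step1(fit, 4000, seed = 3)
  b0s <- vapply(drL, function(z) z$params$beta0, 0)
  expect_lt(abs(mean(b0s) - fit$phi[["beta0"]]),
            3 * sd(b0s) / sqrt(4000))
  # determinism given the seed
  drA <- draw_step1(fit, 3, seed = 9)
  drB <- draw_step1(fit, 3, seed = 9)
  expect_identical(drA, drB)
})

test_that("MCMC draws satisfy parameter invariants and support thinning", {
  sc <- ema_scenario(n_subjects = 12)
  d <- generate_dataset(sc, seed = 6)
  fit <- suppressWarnings(
    fit_mcmc("mels", d, outcome = "y", mean_covariates = c("x1", "x2"),
             config = fast_cfg(adapt = 150, burn = 150, iter = 200),
             seed = 7))
  expect_equal(nrow(fit$draws), 400)
  expect_true(all(fit$draws[, "sigma_v0"] > 0))
  expect_true(all(abs(fit$draws[, "rho_v0v1"]) < 1))
  dr <- draw_step1(fit, 10, seed = 1)
  expect_length(dr, 10)
  for (l in c(1, 5, 10)) {
    expect_s3_class(validate_params(dr[[l]]$params), "mels_params")
    expect_length(dr[[l]]$effects$v0, 12)
  }
  expect_error(draw_step1(fit, 10000), "exceeds")
  # degenerate data refuses to fit
  d_allmiss <- d
  d_allmiss$y <- NA_real_
  expect_error(fit_mcmc("mels", d_allmiss, mean_covariates = "x1"),
               "no observed outcomes")
})

test_that("MCMC and ML give near-identical RILM results with diffuse priors", {
  d <- make_rilm_data(30, 10, seed = 8)
  ml <- fit_rilm_ml(d, outcome = "y", mean_covariates = c("x1", "x2"))
  mc <- suppressWarnings(
    fit_mcmc("rilm", d, outcome = "y", mean_covariates = c("x1", "x2"),
             config = fast_cfg(adapt = 300, burn = 300, iter = 600),
             seed = 9))
  for (par in c("beta0", "beta_x1", "beta_x2", "alpha0")) {
    post <- mc$summary[mc$summary$parameter == par, ]
    ml_est <- ml$summary$estimate[ml$summary$parameter == par]
    expect_lt(abs(post$mean - ml_est), 3 * post$sd)
  }
  post_sv <- mc$summary[mc$summary$parameter == "sigma_v0", ]
  expect_lt(abs(post_sv$mean - ml$estimates[["sigma_v0"]]), 3 * post_sv$sd)
})
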