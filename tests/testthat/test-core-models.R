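test_that("parameter constructors enforce their invariants", {
  expect_error(rilm_params(beta0 = 0, alpha0 = 0, sigma_v0 = -1), "sigma_v0")
  expect_error(mels_params(beta0 = 0, alpha0 = 0, sigma_v0 = 1, sigma_v1 = 1,
                           rho_v0v1 = 1), "rho_v0v1")
  expect_error(spmels_params(beta0 = 0, alpha0 = 0, tau0 = 0, gamma = 0,
                             delta = 0, sigma_eta0 = 1, sigma_eta1 = 0,
                             sigma_lambda = 1), "sigma_eta1")
  p <- spmels_params(beta0 = 0, alpha0 = 0, tau0 = 0, gamma = -0.5,
                     delta = 0.5, sigma_eta0 = 1, sigma_eta1 = 0.5,
                     rho_eta0eta1 = -0.2, sigma_lambda = 1)
  expect_s3_class(p, "spmels_params")
  expect_identical(model_kind(p), "spmels")
  S <- effects_covariance(p)
  expect_equal(S["eta0", "lambda"], 0)       # lambda independent of etas
  expect_gt(min(eigen(S)$values), 0)
})

test_that("SPMELS subject effects satisfy the loading decomposition", {
  set.seed(1)
  lam <- rnorm(5); e0 <- rnorm(5); e1 <- rnorm(5)
  eff <- subject_effects(eta0 = e0, eta1 = e1, lam = lam,
                         gamma = -0.5, delta = 0.5)
  expect_equal(eff$v0, -0.5 * lam + e0)
  expect_equal(eff$v1, 0.5 * lam + e1)
})

test_that("ws_variance matches the model formulas and is log-invertible", {
  expect_equal(ws_variance(rilm_params(beta0 = 0, alpha0 = log(4),
                                       sigma_v0 = 1)), 4)
  pm <- mels_params(beta0 = 0, alpha0 = 0, alpha = c(x = 1), sigma_v0 = 1,
                    sigma_v1 = 1)
  expect_equal(ws_variance(pm, x_row = 0.5, effects_row = list(v1 = -0.5)), 1)
  ps <- spmels_params(beta0 = 0, alpha0 = 0, tau0 = 0, gamma = 0, delta = 0.7,
                      sigma_eta0 = 1, sigma_eta1 = 1, sigma_lambda = 1)
  expect_equal(ws_variance(ps, effects_row = list(eta1 = 0.3, lam = 1)),
               exp(1))
  expect_error(ws_variance(pm, x_row = c(1, 2), effects_row = list(v1 = 0)),
               "length")
  # invertibility: log of the variance is exactly the linear predictor
  set.seed(7)
  for (rep in 1:20) {
    a0 <- rnorm(1); a <- rnorm(2); x <- rnorm(2); v1 <- rnorm(1)
    p <- mels_params(beta0 = 0, alpha0 = a0, alpha = c(u = a[1], w = a[2]),
                     sigma_v0 = 1, sigma_v1 = 1)
    lp <- a0 + sum(a * x) + v1
    expect_equal(log(ws_variance(p, x, list(v1 = v1))), lp, tolerance = 1e-12)
  }
})

test_that("missingness_prob is the logistic of its predictor and monotone", {
  expect_equal(missingness_prob(0), 0.5)
  expect_equal(missingness_prob(log(3)), 0.75)
  expect_equal(missingness_prob(-1e6), 0, tolerance = 1e-12)
  expect_error(missingness_prob(0, tau = c(1, 2), t_row = 1), "length")
  p1 <- missingness_prob(0.2, tau = c(0.1), t_row = 1, lam_i = 0)
  expect_gt(missingness_prob(0.5, tau = c(0.1), t_row = 1, lam_i = 0), p1)
  expect_gt(missingness_prob(0.2, tau = c(0.1), t_row = 1, lam_i = 1), p1)
})

test_that("loglik_y sums per-row normal log densities over observed rows", {
  d <- tiny_dataset()
  # single standard-normal observation at its conditional mean
  d1 <- d[1, ]; d1$y <- 0; d1$x1 <- 0; d1$x2 <- 0; d1$subject <- 1L
  d1 <- as_ema_dataset(as.data.frame(d1))
  p <- rilm_params(beta0 = 0, beta = c(x1 = 1), alpha0 = 0, sigma_v0 = 1)
  eff <- subject_effects(v0 = 0)
  expect_equal(loglik_y(p, d1, eff), -0.5 * log(2 * pi), tolerance = 1e-9)
  # additivity over iid rows
  d2 <- rbind(as.data.frame(d1), as.data.frame(d1))
  expect_equal(loglik_y(p, d2, eff), 2 * loglik_y(p, d1, eff))
  # random instances vs the brute-force per-row oracle
  set.seed(3)
  for (kind in c("rilm", "mels", "spmels")) {
    params <- switch(kind,
      rilm = rilm_params(beta0 = 0.3, beta = c(x1 = 0.5, x2 = -0.2),
                         alpha0 = 0.1, sigma_v0 = 1),
      mels = mels_params(beta0 = 0.3, beta = c(x1 = 0.5, x2 = -0.2),
                         alpha0 = 0.1, alpha = c(x1 = 0.2), sigma_v0 = 1,
                         sigma_v1 = 0.5, rho_v0v1 = -0.3),
      spmels = spmels_params(beta0 = 0.3, beta = c(x1 = 0.5), alpha0 = 0.1,
                             alpha = c(x1 = 0.2), tau0 = -1,
                             tau = c(day = 0.1), gamma = -0.4, delta = 0.6,
                             sigma_eta0 = 1, sigma_eta1 = 0.5,
                             rho_eta0eta1 = -0.2, sigma_lambda = 1))
    eff <- draw_subject_effects(params, 3)
    d <- tiny_dataset(seed = 20 + nchar(kind))
    d$y[5] <- NA; d$m[5] <- 1L
    expect_equal(loglik_y(params, d, eff),
                 loglik_y_rowsum_oracle(params, d, eff), tolerance = 1e-10)
  }
})

test_that("loglik_missing counts every scheduled occasion exactly once", {
  p <- spmels_params(beta0 = 0, alpha0 = 0, tau0 = 0, tau = c(day = 0),
                     gamma = 0, delta = 0, sigma_eta0 = 1, sigma_eta1 = 1,
                     sigma_lambda = 1)
  d <- tiny_dataset(N = 2, n_per = 5)   # 10 occasions
  eff <- subject_effects(eta0 = c(0, 0), eta1 = c(0, 0), lam = c(0, 0),
                         gamma = 0, delta = 0)
  expect_equal(loglik_missing(p, d, eff), 10 * log(0.5), tolerance = 1e-12)
  d1 <- d[1, ]; d1$m <- 1L; d1$y <- NA; d1$day <- 1
  p2 <- spmels_params(beta0 = 0, alpha0 = 0, tau0 = log(3), tau = c(day = 0),
                      gamma = 0, delta = 0, sigma_eta0 = 1, sigma_eta1 = 1,
                      sigma_lambda = 1)
  expect_equal(loglik_missing(p2, d1, eff), log(0.75), tolerance = 1e-12)
  # random instance vs elementwise Bernoulli oracle
  set.seed(9)
  p3 <- spmels_params(beta0 = 0, alpha0 = 0, tau0 = -0.5,
                      tau = c(day = 0.2, beep1 = 0.4), gamma = 0, delta = 0,
                      sigma_eta0 = 1, sigma_eta1 = 1, sigma_lambda = 1)
  d3 <- tiny_dataset(N = 4, n_per = 6, seed = 2)
  d3$m <- rbinom(nrow(d3), 1, 0.3)
  d3$y[d3$m == 1] <- NA
  eff3 <- draw_subject_effects(p3, 4)
  expect_equal(loglik_missing(p3, d3, eff3),
               loglik_missing_elementwise_oracle(p3, d3, eff3),
               tolerance = 1e-12)
  d3$m[2] <- 2
  expect_error(loglik_missing(p3, d3, eff3), "0/1|\\{0,1\\}")
})

test_that("SPMELS with zero loadings equals MELS plus missingness plus lambda", {
  set.seed(14)
  for (rep in 1:5) {
    d <- tiny_dataset(N = 3, n_per = 4, seed = 30 + rep)
    d$m <- rbinom(nrow(d), 1, 0.2); d$y[d$m == 1] <- NA
    sp <- spmels_params(beta0 = 0.2, beta = c(x1 = 0.5), alpha0 = 0.1,
                        alpha = c(x1 = 0.2), tau0 = -1, tau = c(day = 0.2),
                        gamma = 0, delta = 0, sigma_eta0 = 1.1,
                        sigma_eta1 = 0.6, rho_eta0eta1 = -0.25,
                        sigma_lambda = 0.9)
    me <- mels_params(beta0 = 0.2, beta = c(x1 = 0.5), alpha0 = 0.1,
                      alpha = c(x1 = 0.2), sigma_v0 = 1.1, sigma_v1 = 0.6,
                      rho_v0v1 = -0.25)
    eff <- draw_subject_effects(sp, 3)
    eff_m <- subject_effects(v0 = eff$eta0, v1 = eff$eta1)
    lhs <- joint_log_density(sp, d, eff)
    rhs <- joint_log_density(me, d, eff_m) + loglik_missing(sp, d, eff) +
      sum(dnorm(eff$lam, 0, sp$sigma_lambda, log = TRUE))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("MELS approaches RILM as the scale effect vanishes", {
  d <- tiny_dataset(N = 3, n_per = 4, seed = 40)
  ri <- rilm_params(beta0 = 0.2, beta = c(x1 = 0.5), alpha0 = 0.1,
                    sigma_v0 = 1.1)
  me <- mels_params(beta0 = 0.2, beta = c(x1 = 0.5), alpha0 = 0.1,
                    sigma_v0 = 1.1, sigma_v1 = 1e-8, rho_v0v1 = 0)
  eff <- subject_effects(v0 = c(0.4, -0.2, 0.1))
  eff_m <- subject_effects(v0 = eff$v0, v1 = rep(0, 3))
  lhs <- joint_log_density(me, d, eff_m)
  # the vanishing scale effect contributes only its own density at zero
  rhs <- joint_log_density(ri, d, eff) + dnorm(0, 0, 1e-8, log = TRUE) * 3
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("quadrature-marginalized joint density matches brute-force integration", {
  d1 <- data.frame(subject = 1L, day = 1:2, beep = 1:2, beep1 = c(1L, 0L),
                   beep6 = c(0L, 1L), x2 = 0.3, x1 = c(0.5, -0.4),
                   y = c(0.7, -0.1), m = 0L)
  d1 <- as_ema_dataset(d1)
  ri <- rilm_params(beta0 = 0.2, beta = c(x1 = 0.5), alpha0 = -0.2,
                    sigma_v0 = 0.8)
  me <- mels_params(beta0 = 0.2, beta = c(x1 = 0.5), alpha0 = -0.2,
                    alpha = c(x1 = 0.3), sigma_v0 = 0.8, sigma_v1 = 0.5,
                    rho_v0v1 = -0.3)
  sp <- spmels_params(beta0 = 0.2, beta = c(x1 = 0.5), alpha0 = -0.2,
                      alpha = c(x1 = 0.3), tau0 = -1, tau = c(day = 0.2),
                      gamma = -0.5, delta = 0.4, sigma_eta0 = 0.8,
                      sigma_eta1 = 0.5, rho_eta0eta1 = -0.3,
                      sigma_lambda = 0.9)
  for (p in list(ri, me, sp)) {
    gh <- marginal_loglik_gh(p, d1, n_nodes = if (model_kind(p) == "spmels")
      25 else 40)
    bf <- marginal_loglik_bruteforce(p, d1)
    expect_equal(gh, bf, tolerance = 1e-6)
  }
  # RILM also has a closed-form marginal (compound-symmetry normal)
  S <- exp(ri$alpha0) * diag(2) + ri$sigma_v0^2
  mu <- ri$beta0 + ri$beta[["x1"]] * d1$x1
  closed <- mvtnorm_logd(d1$y - mu, S)
  expect_equal(marginal_loglik_bruteforce(ri, d1), as.numeric(closed),
               tolerance = 1e-8)
})

test_that("variance_share matches its formula and edge cases", {
  expect_equal(variance_share(0, 1, 1), 0)
  expect_equal(variance_share(1, 1, 1), 0.5)
  expect_error(variance_share(0, 1, 0), "undefined")
  expect_equal(100 * variance_share(-0.46, 1.39, 1.66),
               100 * 0.6394^2 / (0.6394^2 + 1.66^2), tolerance = 1e-12)
  expect_equal(variance_share(2, 1, 1e-9), 1, tolerance = 1e-6)
})
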