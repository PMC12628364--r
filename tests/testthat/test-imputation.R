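test_that("imputing a complete column returns the input in every copy", {
  d <- tiny_dataset(N = 4, n_per = 5)
  fit <- suppressWarnings(
    fit_rilm_ml(d, outcome = "y", mean_covariates = c("x1", "x2")))
  dr <- draw_step1(fit, 4, seed = 1)
  imp <- impute_variable(d, dr, "y", seed = 2)
  expect_equal(ncol(imp$copies), 4)
  for (l in 1:4) expect_identical(imp$copies[, l], d$y)
})

test_that("a degenerate WS variance collapses draws to the conditional mean", {
  d <- tiny_dataset(N = 4, n_per = 5)
  d$y[c(3, 9)] <- NA; d$m[c(3, 9)] <- 1L
  p <- rilm_params(beta0 = 1, beta = c(x1 = 0.5, x2 = 0.2), alpha0 = -60,
                   sigma_v0 = 1)
  eff <- subject_effects(v0 = c(0.3, -0.1, 0.2, 0))
  dr <- structure(list(list(params = p, effects = eff)),
                  class = "step1_draws", kind = "rilm", outcome = "y")
  imp <- impute_variable(d, dr, "y", seed = 3)
  mu3 <- 1 + 0.5 * d$x1[3] + 0.2 * d$x2[3] + eff$v0[d$subject[3]]
  expect_equal(imp$copies[3, 1], mu3, tolerance = 1e-6)
})

test_that("observed cells are preserved bit-exactly through the pipeline", {
  sc <- ema_scenario(n_subjects = 10)
  d <- generate_dataset(sc, seed = 31)
  si <- suppressWarnings(
    sequential_impute(d, "rilm", "rilm", L = 5, seed = 4, mode = "fast"))
  obs <- which(d$m == 0)
  for (l in 1:5) {
    cd <- completed_dataset(si, l)
    expect_identical(cd$y[obs], d$y[obs])
    expect_identical(cd$x1[obs], d$x1[obs])
    expect_false(anyNA(cd$y))
    expect_false(anyNA(cd$x1))
  }
  pooled <- pool_mean(si)
  expect_identical(pooled$y[obs], d$y[obs])
  # between-imputation spread exists at imputed cells
  miss <- which(d$m == 1)
  spread <- apply(si$y$copies[miss, , drop = FALSE], 1, sd)
  expect_true(all(spread >= 0))
  expect_gt(mean(spread), 0)
})

test_that("pool_mean is the cellwise arithmetic mean", {
  imp <- structure(list(copies = cbind(c(1, 5), c(3, 5)), target = "y",
                        kind = "rilm", seed = 1, missing_rows = 1L),
                   class = "imputation_set")
  expect_equal(pool_mean(imp), c(2, 5))
  # identical copies pool to themselves
  imp2 <- imp; imp2$copies <- cbind(c(1, 5), c(1, 5))
  expect_equal(pool_mean(imp2), c(1, 5))
  # elementwise oracle on a random set
  set.seed(5)
  M <- matrix(rnorm(60), 12, 5)
  imp3 <- imp; imp3$copies <- M
  expect_equal(pool_mean(imp3),
               vapply(1:12, function(r) mean(M[r, ]), 0), tolerance = 1e-15)
})

test_that("single imputation is the L = 1 collapse of the multiple scheme", {
  sc <- ema_scenario(n_subjects = 8)
  d <- generate_dataset(sc, seed = 32)
  si <- suppressWarnings(
    sequential_impute(d, "rilm", "rilm", L = 1, seed = 6, mode = "fast"))
  expect_equal(si$L, 1)
  cd <- completed_dataset(si, 1)
  expect_false(anyNA(cd$y))
  expect_equal(pool_mean(si)$y, cd$y)
})

test_that("imputation requires its covariates and flags circularity", {
  sc <- ema_scenario(n_subjects = 8)
  d <- generate_dataset(sc, seed = 33)
  fit <- fit_rilm_ml(d, outcome = "y", mean_covariates = c("x1", "x2"))
  dr <- draw_step1(fit, 2, seed = 1)
  expect_error(impute_variable(d, dr, "y"), "impute it first")
  expect_error(sequential_impute(d, "rilm", "rilm",
                                 x1_covariates = c("x1", "x2")), "circular")
})

test_that("MCAR RILM imputations center on the conditional-mean oracle", {
  # truth-generated RILM data with MCAR masking; the pooled imputation at a
  # missing cell should match beta0 + x'beta + v0 within Monte-Carlo error
  set.seed(41)
  N <- 60; n_per <- 12
  d <- data.frame(subject = rep(seq_len(N), each = n_per), day = 1L,
                  beep = 1L, beep1 = 1L, beep6 = 0L,
                  x2 = rep(rnorm(N), each = n_per), x1 = rnorm(N * n_per))
  v0 <- rnorm(N, 0, 0.8)
  mu_true <- 1 + 0.5 * d$x1 + 0.3 * d$x2 + v0[d$subject]
  d$y <- mu_true + rnorm(N * n_per, 0, 1)
  mask <- rbinom(N * n_per, 1, 0.2) == 1   # MCAR
  y_full <- d$y
  d$y[mask] <- NA
  d$m <- as.integer(mask)
  d <- as_ema_dataset(d)
  fit <- fit_rilm_ml(d, outcome = "y", mean_covariates = c("x1", "x2"))
  dr <- draw_step1(fit, 50, seed = 2)
  imp <- impute_variable(d, dr, "y", seed = 3)
  pooled <- pool_mean(imp)
  resid <- pooled[mask] - mu_true[mask]
  # pooled values are unbiased for the conditional mean; SD per cell is
  # roughly sqrt(sigma_eps^2/L + EB variance), well under 0.5 on average
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(sum(mask)))
})
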