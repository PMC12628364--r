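# Shared fixtures and independent oracles used across test files.

fast_cfg <- function(chains = 2, adapt = 200, burn = 200, iter = 400)
  mcmc_config(chains = chains, adapt = adapt, burn = burn, iter = iter)

# A tiny hand-built EMA dataset (no generator involved).
tiny_dataset <- function(N = 3, n_per = 4, seed = 11) {
  set.seed(seed)
  d <- data.frame(subject = rep(seq_len(N), each = n_per),
                  day = rep(seq_len(n_per), N),
                  beep = 1)
  d$beep1 <- as.integer(d$beep == 1)
  d$beep6 <- 0L
  d$x2 <- rep(round(rnorm(N), 2), each = n_per)
  d$x1 <- round(rnorm(N * n_per), 2)
  d$y <- round(rnorm(N * n_per), 2)
  d$m <- 0L
  as_ema_dataset(d)
}

# Brute-force per-row log-likelihood summation (independent of loglik_y's
# vectorized path): loops over rows and calls dnorm once per observation.
loglik_y_rowsum_oracle <- function(params, data, effects, outcome = "y") {
  tot <- 0
  for (r in seq_len(nrow(data))) {
    yv <- data[[outcome]][r]
    if (is.na(yv)) next
    i <- data$subject[r]
    kind <- model_kind(params)
    xb <- sum(vapply(names(params$beta), function(nm) data[[nm]][r], 0) *
                params$beta)
    if (kind == "spmels") {
      mu <- params$beta0 + xb + effects$eta0[i] + params$gamma * effects$lam[i]
    } else {
      mu <- params$beta0 + xb + effects$v0[i]
    }
    xa <- if (length(params$alpha))
      sum(vapply(names(params$alpha), function(nm) data[[nm]][r], 0) *
            params$alpha) else 0
    lv <- switch(kind,
      rilm = params$alpha0,
      mels = params$alpha0 + xa + effects$v1[i],
      spmels = params$alpha0 + xa + effects$eta1[i] +
        params$delta * effects$lam[i])
    tot <- tot + dnorm(yv, mu, exp(lv / 2), log = TRUE)
  }
  tot
}

# Elementwise Bernoulli oracle for the missingness log-likelihood.
loglik_missing_elementwise_oracle <- function(params, data, effects) {
  tot <- 0
  for (r in seq_len(nrow(data))) {
    i <- data$subject[r]
    tr <- vapply(names(params$tau), function(nm) data[[nm]][r], 0)
    p <- plogis(params$tau0 + sum(tr * params$tau) + effects$lam[i])
    tot <- tot + log(ifelse(data$m[r] == 1, p, 1 - p))
  }
  tot
}

# Marginal likelihood of a 1-subject dataset by Gauss-Hermite tensor
# quadrature of exp(joint_log_density) over the subject's effects.
marginal_loglik_gh <- function(params, data, outcome = "y", n_nodes = 40) {
  S <- effects_covariance(params)
  R <- chol(S)
  gh <- pracma::gaussHermite(n_nodes)
  k <- nrow(S)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), k)))
  logw <- rowSums(matrix(log(gh$w)[grid], nrow(grid), k))
  # effects = sqrt(2) * R' z ; the GH weight absorbs the normal density of z
  vals <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    z <- gh$x[grid[g, ]]
    eff_vec <- sqrt(2) * drop(t(R) %*% z)
    eff <- switch(model_kind(params),
      rilm = subject_effects(v0 = eff_vec[1]),
      mels = subject_effects(v0 = eff_vec[1], v1 = eff_vec[2]),
      spmels = subject_effects(eta0 = eff_vec[1], eta1 = eff_vec[2],
                               lam = eff_vec[3], gamma = params$gamma,
                               delta = params$delta))
    # joint includes the effects density; divide it out and use the GH kernel
    ll_eff <- sum(mvtnorm_logd(eff_vec, S))
    vals[g] <- joint_log_density(params, data, eff, outcome = outcome) - ll_eff
  }
  tot <- vals + logw - k / 2 * log(pi)
  mx <- max(tot)
  mx + log(sum(exp(tot - mx)))
}

mvtnorm_logd <- function(x, S) {
  k <- length(x)
  -0.5 * (k * log(2 * pi) + determinant(S)$modulus +
            drop(t(x) %*% solve(S) %*% x))
}

# Brute-force marginal likelihood by nested adaptive integration of an
# integrand written directly from the model formulas (never calls the
# package's density functions).
marginal_loglik_bruteforce <- function(params, data, outcome = "y") {
  y <- data[[outcome]]
  obs <- which(!is.na(y))
  kind <- model_kind(params)
  xb <- rep(params$beta0, nrow(data))
  for (nm in names(params$beta)) xb <- xb + params$beta[[nm]] * data[[nm]]
  xa <- rep(params$alpha0, nrow(data))
  for (nm in names(params$alpha)) xa <- xa + params$alpha[[nm]] * data[[nm]]
  if (kind == "rilm") {
    f <- function(v0) vapply(v0, function(v) {
      prod(dnorm(y[obs], xb[obs] + v, exp(params$alpha0 / 2))) *
        dnorm(v, 0, params$sigma_v0)
    }, 0)
    return(log(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value))
  }
  if (kind == "mels") {
    s0 <- params$sigma_v0; s1 <- params$sigma_v1; r <- params$rho_v0v1
    outer_f <- function(v0s) vapply(v0s, function(v0) {
      inner <- function(v1) vapply(v1, function(w) {
        prod(dnorm(y[obs], xb[obs] + v0, exp((xa[obs] + w) / 2))) *
          dnorm(w, r * s1 / s0 * v0, s1 * sqrt(1 - r^2))
      }, 0)
      integrate(inner, -Inf, Inf, rel.tol = 1e-10)$value * dnorm(v0, 0, s0)
    }, 0)
    return(log(integrate(outer_f, -Inf, Inf, rel.tol = 1e-9)$value))
  }
  # spmels: integrate over (eta0, eta1, lambda)
  s0 <- params$sigma_eta0; s1 <- params$sigma_eta1; r <- params$rho_eta0eta1
  sl <- params$sigma_lambda
  tl <- rep(params$tau0, nrow(data))
  for (nm in names(params$tau)) tl <- tl + params$tau[[nm]] * data[[nm]]
  f_lam <- function(lams) vapply(lams, function(lam) {
    pm <- plogis(tl + lam)
    lik_m <- prod(ifelse(data$m == 1, pm, 1 - pm))
    f_e0 <- function(e0s) vapply(e0s, function(e0) {
      f_e1 <- function(e1) vapply(e1, function(w) {
        mu <- xb[obs] + e0 + params$gamma * lam
        sd_ <- exp((xa[obs] + w + params$delta * lam) / 2)
        prod(dnorm(y[obs], mu, sd_)) *
          dnorm(w, r * s1 / s0 * e0, s1 * sqrt(1 - r^2))
      }, 0)
      integrate(f_e1, -Inf, Inf, rel.tol = 1e-10)$value * dnorm(e0, 0, s0)
    }, 0)
    lik_m * integrate(f_e0, -Inf, Inf, rel.tol = 1e-9)$value *
      dnorm(lam, 0, sl)
  }, 0)
  log(integrate(f_lam, -Inf, Inf, rel.tol = 1e-8)$value)
}
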