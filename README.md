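# emaimpute

Two-step Bayesian multiple imputation for intensive-longitudinal (EMA)
outcomes, built on mixed-effects location-scale models.

Ecological momentary assessment (EMA) studies prompt subjects several times a
day over multiple days and routinely lose 20–40% of responses — often in ways
tied to the day of study, the time of day, the subject, and sometimes the
unobserved outcome itself. This package imputes such missing outcomes with a
two-step Bayesian scheme over three nested mixed models, for analysts who
want imputations that respect within-subject variance structure and
potentially informative missingness:

* **RILM** — random-intercept linear mixed model:
  `y_ij | v0_i ~ N(β0 + x_ij'β + v0_i, exp(α0))`, constant within-subject
  (WS) variance.
* **MELS** — mixed-effects location-scale model: a log-linear WS-variance
  submodel `σ²_ij = exp(α0 + x_ij'α + v1_i)` with a random scale effect
  `v1_i` correlated with the location effect `v0_i`.
* **SPMELS** — shared-parameter MELS: adds a random-intercept logistic model
  for the missingness indicator,
  `m_ij ~ Bern(logit⁻¹(τ0 + t_ij'τ + λ_i))`, whose random missing effect
  loads on the outcome's location and scale
  (`v0_i = γλ_i + η0_i`, `v1_i = δλ_i + η1_i`), so missingness may be
  missing-not-at-random.

Imputation follows the two-step factorization
`P(y_miss | y_obs) = ∫ P(y_miss | y_obs, θ) P(θ | y_obs) dθ`: Step 1 draws
`θ (and subject effects) ~ P(θ | y_obs)` (MCMC via JAGS, or a closed-form ML
surrogate for RILM); Step 2 draws `ŷ_miss ~ P(y_miss | y_obs, θ̂)`; L repeats
give a multiple imputation, pooled cellwise by `pool_mean()`. The package
also ships the synthetic EMA-study generator with calibrated informative
missingness, a simulation-study harness (bias, coverage, imputation error,
best/worst difference ratios), posterior predictive checks with a WS-variance
discrepancy, and leave-one-out ELPD model comparison.

## Worked example

Generate a synthetic EMA study (20 subjects × 5 days × 6 beeps, ~20%
informatively missing, the missingness intercept calibrated by Gauss–Hermite
root-finding), then impute the time-varying covariate and the outcome
sequentially with MELS:

```r
library(emaimpute)

scenario <- ema_scenario()
data <- generate_dataset(scenario, seed = 7)
mean(data$m)
#> 0.2133333   # realized missing fraction, target 20%

imp <- sequential_impute(
  data, x1_kind = "mels", y_kind = "mels", L = 10, seed = 7, mode = "fast",
  config = mcmc_config(chains = 2, adapt = 300, burn = 300, iter = 600))
imp
#> <sequential_imputation> x1: MELS, y: MELS, L = 10 (fast mode)

completed <- pool_mean(imp)            # cellwise mean of the 10 copies
imputation_error(completed, data)      # MSE vs the retained true values
#> 0.5969847
```

The Step-1 fit of the outcome model recovers the generating structure
(true values: `beta_x1 = 0.5`, `alpha0 = 0`, `alpha_x1 = 0.3`):

```r
fit <- imp$fits$y[[1]]
fit$summary[fit$summary$parameter %in%
              c("beta_x1", "alpha0", "alpha_x1", "sigma_v1"), ]
#>   parameter       mean       q2.5     q97.5     rhat
#>      alpha0 -0.0252727 -0.5113848 0.4836168 1.047032
#>    alpha_x1  0.2347875  0.1294091 0.3376870 1.008649
#>     beta_x1  0.4574629  0.3791890 0.5283942 1.000956
#>    sigma_v1  0.7876502  0.5299696 1.2201461 1.001462
```

`beta_x1` means a one-unit increase in the time-varying covariate raises the
expected outcome by ≈ 0.46; `alpha_x1` means it also raises the log WS
variance by ≈ 0.23 — the heteroscedasticity that a constant-variance
imputation model cannot express. The 95% intervals cover the generating
values, and split-R-hat is at or below 1.05.

Model checking and comparison:

```r
d_complete <- data; d_complete$x1 <- pool_mean(imp$x1)  # complete covariate
ppc <- ppc_pvalue(fit, d_complete, Lppc = 1000, seed = 1)  # per-subject p_com
cmp <- elpd_compare(list(rilm = fit_r, mels = fit_m), data) # higher is better
```

A small command-line wrapper is installed at `inst/cli/emaimpute` with
subcommands `simulate`, `fit`, `impute`, `study`, `ppc`.

## The simulation study

`run_study(scenario, K, L)` repeats generation → fitting → imputation K
times, fits all three models for both incomplete variables, imputes the
outcome under every model pairing in single- and multiple-imputation arms,
and returns tidy tables of bias, 95% interval coverage, mean imputation
error, and best/worst difference ratios. See the methods vignette
(`vignettes/two-step-imputation.Rmd`) for the model specification choices,
the generator's defaults and what they do and do not emulate, and the
package's own findings at reduced scale.

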