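#' Impute one variable from Step-1 draws (Step 2)
#'
#' For each Step-1 draw \eqn{l} and each occasion where `target` is missing,
#' draws from the model's conditional distribution
#' \eqn{N(\beta_0 + x'\beta + v_{0,i}, \sigma^2_{\epsilon ij})} (SPMELS:
#' mean \eqn{\beta_0 + x'\beta + \eta_{0,i} + \gamma\lambda_i}) evaluated at
#' that draw's parameters and subject effects. Observed values are passed
#' through untouched in every copy.
#'
#' @param data Dataset containing the target column and all covariates the
#'   draws' model requires (impute covariates first if they are missing —
#'   see [sequential_impute()]).
#' @param step1_draws A `step1_draws` object from [draw_step1()].
#' @param target Column to impute.
#' @param seed Integer seed.
#' @return An `imputation_set`: list with `copies` (matrix, rows of `data`
#'   by L), `target`, `kind`, `seed`.
#' @export
impute_variable <- function(data, step1_draws, target, seed = 1L) {
  stopifnot(inherits(step1_draws, "step1_draws"))
  L <- length(step1_draws)
  obs_vals <- data[[target]]
  miss <- which(is.na(obs_vals))
  copies <- matrix(rep(obs_vals, L), ncol = L)
  if (length(miss)) {
    cov_needed <- unique(c(names(step1_draws[[1]]$params$beta),
                           names(step1_draws[[1]]$params$alpha)))
    for (cc in cov_needed)
      if (anyNA(data[[cc]][miss]))
        stop("covariate '", cc, "' is missing at rows to impute; ",
             "impute it first (sequential_impute)")
    set.seed(as.integer(seed))
    dm <- data[miss, , drop = FALSE]
    for (l in seq_len(L)) {
      pr <- row_predictors(step1_draws[[l]]$params, dm,
                           step1_draws[[l]]$effects)
      copies[miss, l] <- stats::rnorm(length(miss), pr$mu, exp(pr$log_var / 2))
    }
  }
  structure(list(copies = copies, target = target,
                 kind = attr(step1_draws, "kind"), seed = seed,
                 missing_rows = miss),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> '%s' by %s: L = %d copies, %d imputed cells\n",
              x$target, toupper(x$kind), ncol(x$copies), length(x$missing_rows)))
  invisible(x)
}

fit_model <- function(kind, data, outcome, mean_covariates,
                      var_covariates = mean_covariates,
                      method_rilm = "ml", config = mcmc_config(), seed = 1L) {
  if (kind == "rilm" && method_rilm == "ml")
    fit_rilm_ml(data, outcome = outcome, mean_covariates = mean_covariates)
  else
    fit_mcmc(kind, data, outcome = outcome, mean_covariates = mean_covariates,
             var_covariates = var_covariates, config = config, seed = seed)
}

#' Sequential imputation of a covariate and the outcome
#'
#' The two-variable scheme of the simulation design: fit a model for `x1`
#' on the available covariates and impute it, then fit a model for `y` that
#' uses the completed `x1` and impute `y`, keeping the pairing of the l-th
#' `x1` copy with the l-th `y` draw.
#'
#' Two refit policies are available. `"proper"` refits the `y` model on each
#' of the L completed datasets and takes one Step-1 draw per fit. `"fast"`
#' fits the `y` model once (on completed copy 1) and pairs its L Step-1
#' draws with the L completed copies. When `x1` and `y` are missing on the
#' same occasions — as in this package's generative design — the `y` model's
#' likelihood rows never contain imputed `x1`, so both policies target the
#' same fit and `"fast"` is exact.
#'
#' @param data An `ema_dataset`.
#' @param x1_kind,y_kind Model kinds (`"rilm"`, `"mels"`, `"spmels"`) for
#'   the two variables.
#' @param L Number of imputations (1 = single imputation).
#' @param seed Integer seed.
#' @param mode Refit policy, `"proper"` or `"fast"`.
#' @param method_rilm `"ml"` (default, the computationally cheap surrogate)
#'   or `"mcmc"` for RILM Step-1 fits.
#' @param config [mcmc_config()] for the MCMC fits.
#' @param x1_covariates,y_covariates Mean-submodel covariates for each
#'   variable (the missingness submodel uses `day`, `beep1`, `beep6`).
#' @param x1_var_covariates,y_var_covariates WS-variance submodel covariates.
#'   Defaults keep the variance model on the continuous covariates only,
#'   matching the generative design's variance structure; the mean model
#'   still uses every available covariate.
#' @return A `sequential_imputation` object: `x1` and `y` are
#'   `imputation_set`s with aligned copies; `fits` holds the Step-1 fits.
#' @export
sequential_impute <- function(data, x1_kind, y_kind, L = 10, seed = 1L,
                              mode = c("proper", "fast"),
                              method_rilm = "ml", config = mcmc_config(),
                              x1_covariates = c("x2", "day", "beep1", "beep6"),
                              y_covariates = c("x1", "x2", "day", "beep1", "beep6"),
                              x1_var_covariates = "x2",
                              y_var_covariates = c("x1", "x2")) {
  mode <- match.arg(mode)
  stopifnot(L >= 1)
  if ("x1" %in% x1_covariates)
    stop("circular dependency: x1 cannot be its own covariate")
  seed <- as.integer(seed)

  fit_x1 <- fit_model(x1_kind, data, "x1", x1_covariates,
                      var_covariates = x1_var_covariates,
                      method_rilm = method_rilm, config = config, seed = seed)
  draws_x1 <- draw_step1(fit_x1, L, seed = seed + 1L)
  imp_x1 <- impute_variable(data, draws_x1, "x1", seed = seed + 2L)

  y_copies <- matrix(rep(data$y, L), ncol = L)
  miss_y <- which(is.na(data$y))
  fits_y <- list()
  if (mode == "fast") {
    d1 <- data
    d1$x1 <- imp_x1$copies[, 1]
    fit_y <- fit_model(y_kind, d1, "y", y_covariates,
                       var_covariates = y_var_covariates,
                       method_rilm = method_rilm, config = config,
                       seed = seed + 3L)
    draws_y <- draw_step1(fit_y, L, seed = seed + 4L)
    for (l in seq_len(L)) {
      dl <- data
      dl$x1 <- imp_x1$copies[, l]
      one <- structure(draws_y[l], class = "step1_draws",
                       kind = attr(draws_y, "kind"), outcome = "y")
      y_copies[, l] <- impute_variable(dl, one, "y",
                                       seed = seed + 100L + l)$copies[, 1]
    }
    fits_y <- list(fit_y)
  } else {
    for (l in seq_len(L)) {
      dl <- data
      dl$x1 <- imp_x1$copies[, l]
      fit_l <- fit_model(y_kind, dl, "y", y_covariates,
                         var_covariates = y_var_covariates,
                         method_rilm = method_rilm, config = config,
                         seed = seed + 10L * l)
      draw_l <- draw_step1(fit_l, 1, seed = seed + 10L * l + 1L)
      y_copies[, l] <- impute_variable(dl, draw_l, "y",
                                       seed = seed + 100L + l)$copies[, 1]
      fits_y[[l]] <- fit_l
    }
  }
  imp_y <- structure(list(copies = y_copies, target = "y", kind = y_kind,
                          seed = seed, missing_rows = miss_y),
                     class = "imputation_set")
  structure(list(x1 = imp_x1, y = imp_y, data = data,
                 x1_kind = x1_kind, y_kind = y_kind, L = L, mode = mode,
                 fits = list(x1 = fit_x1, y = fits_y)),
            class = "sequential_imputation")
}

#' @export
print.sequential_imputation <- function(x, ...) {
  cat(sprintf("<sequential_imputation> x1: %s, y: %s, L = %d (%s mode)\n",
              toupper(x$x1_kind), toupper(x$y_kind), x$L, x$mode))
  invisible(x)
}

#' The l-th completed dataset of a sequential imputation
#'
#' @param imps A `sequential_imputation`.
#' @param l Copy index.
#' @return The input dataset with `x1` and `y` completed by copy `l`.
#' @export
completed_dataset <- function(imps, l = 1) {
  stopifnot(l >= 1, l <= imps$L)
  d <- imps$data
  d$x1 <- imps$x1$copies[, l]
  d$y <- imps$y$copies[, l]
  d
}

#' Pool imputations by cellwise averaging
#'
#' The final multiple-imputation value of each missing cell is the
#' arithmetic mean of its L imputed values; observed cells pass through.
#'
#' @param imps An `imputation_set` or `sequential_imputation`.
#' @return For an `imputation_set`, the pooled column (numeric vector); for
#'   a `sequential_imputation`, the completed dataset with pooled `x1` and
#'   `y`.
#' @export
pool_mean <- function(imps) UseMethod("pool_mean")

#' @export
pool_mean.imputation_set <- function(imps) {
  if (ncol(imps$copies) == 0L) stop("empty imputation set")
  rowMeans(imps$copies)
}

#' @export
pool_mean.sequential_imputation <- function(imps) {
  d <- imps$data
  d$x1 <- pool_mean(imps$x1)
  d$y <- pool_mean(imps$y)
  d
}
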