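#' Long-format EMA dataset
#'
#' An EMA dataset is a long-format data frame with one row per scheduled
#' subject-occasion. Required columns: `subject` (integer codes 1..N), `day`,
#' `beep`, `beep1`/`beep6` (first/last-beep indicators), `x2` (time-constant
#' covariate), `x1` (time-varying covariate, possibly `NA`), `y` (outcome,
#' possibly `NA`) and `m` (missingness indicator: 1 means the outcome is
#' missing at that scheduled occasion). Optional `true_*` columns retain
#' pre-masking values for simulation error computation.
#'
#' `as_ema_dataset()` validates an existing data frame: it derives `m` from
#' `y`'s missingness when absent, checks that `x2` is constant within
#' subject, and that `m` agrees with the observed/missing pattern of `y`.
#'
#' @param data A data.frame.
#' @param require_x1 Validate the `x1` column too (default TRUE).
#' @return The validated data.frame with class `ema_dataset` prepended.
#' @export
as_ema_dataset <- function(data, require_x1 = TRUE) {
  stopifnot(is.data.frame(data))
  req <- c("subject", "day", "beep", "beep1", "beep6", "x2", "y")
  if (require_x1) req <- c(req, "x1")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("EMA dataset lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(data$subject))
    stop("NA subject at row(s): ",
         paste(utils::head(which(is.na(data$subject)), 5), collapse = ", "))
  data$subject <- as.integer(data$subject)
  if (!setequal(unique(data$subject), seq_len(max(data$subject))))
    stop("subject codes must be 1..N without gaps")
  if (is.null(data$m)) data$m <- as.integer(is.na(data$y))
  if (!all(data$m %in% c(0, 1)))
    stop("m outside {0,1} at row(s): ",
         paste(utils::head(which(!(data$m %in% c(0, 1))), 5), collapse = ", "))
  bad_m <- which((data$m == 1) != is.na(data$y))
  if (length(bad_m))
    stop("m disagrees with y's missingness at row(s): ",
         paste(utils::head(bad_m, 5), collapse = ", "))
  x2_sd <- tapply(data$x2, data$subject, function(z) diff(range(z)))
  if (any(x2_sd > 1e-12))
    stop("x2 is not constant within subject(s): ",
         paste(utils::head(names(x2_sd)[x2_sd > 1e-12], 5), collapse = ", "))
  if (!inherits(data, "ema_dataset")) class(data) <- c("ema_dataset", class(data))
  data
}

#' Number of subjects in an EMA dataset
#' @param data An `ema_dataset`.
#' @return Integer N.
#' @export
n_subjects <- function(data) max(data$subject)

#' Read an EMA dataset from a long-format CSV file
#'
#' Expects a header row; missing cells may be empty or `"NA"`. The
#' missingness indicator `m` is derived from `y` when the column is absent.
#'
#' @param path Path to a CSV file.
#' @return A validated `ema_dataset`.
#' @export
read_ema_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  as_ema_dataset(df)
}

#' Write an EMA dataset to CSV
#'
#' Missing cells are written as empty strings for interoperability.
#'
#' @param data An `ema_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ema_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Declarative column transforms
#'
#' Applies a list of transforms to dataset columns before modelling:
#' `sqrt(column)` (square-root transform, e.g. for right-skewed activity
#' minutes), `scale(column, factor)` (multiply, e.g. age/10), and
#' `interaction(col_a, col_b, ...)` (product term, appended as
#' `col_a.col_b`). Transform provenance is recorded in the
#' `"transforms"` attribute.
#'
#' @param data A data.frame.
#' @param transforms A list; each element is a list with `op` in
#'   `c("sqrt", "scale", "interaction")`, `cols` (character), and for
#'   `scale` a `factor`.
#' @return The transformed data.frame.
#' @examples
#' d <- data.frame(age = 58, mvpa = c(0, 4, 9))
#' d <- preprocess(d, list(list(op = "sqrt", cols = "mvpa"),
#'                         list(op = "scale", cols = "age", factor = 1/10)))
#' @export
preprocess <- function(data, transforms) {
  for (tr in transforms) {
    op <- match.arg(tr$op, c("sqrt", "scale", "interaction"))
    cols <- tr$cols
    miss <- setdiff(cols, names(data))
    if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "))
    if (op == "sqrt") {
      for (cc in cols) {
        neg <- which(data[[cc]] < 0)
        if (length(neg))
          stop("sqrt of negative values in '", cc, "' at row(s): ",
               paste(utils::head(neg, 5), collapse = ", "))
        data[[cc]] <- sqrt(data[[cc]])
      }
    } else if (op == "scale") {
      stopifnot(is.numeric(tr$factor))
      for (cc in cols) data[[cc]] <- data[[cc]] * tr$factor
    } else {
      stopifnot(length(cols) >= 2)
      data[[paste(cols, collapse = ".")]] <- Reduce(`*`, data[cols])
    }
  }
  attr(data, "transforms") <- c(attr(data, "transforms"), transforms)
  data
}

#' @export
print.ema_dataset <- function(x, ...) {
  cat(sprintf("<ema_dataset> %d rows, %d subjects, %.1f%% occasions missing\n",
              nrow(x), n_subjects(x), 100 * mean(x$m)))
  NextMethod()
}
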