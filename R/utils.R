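## Small shared helpers. Internal.

# Round to the nearest multiple of `unit`, ties (x.5 units) rounding up.
# base round() rounds half to even, which is not what a monitor-time grid
# should do.
round_half_up <- function(x, unit = 5) {
  floor(x / unit + 0.5) * unit
}

# Population variance (divide by n). stats::var divides by n - 1.
pop_var <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

# OLS slope of y on x; NA when fewer than 2 points or degenerate x.
ols_slope <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) return(NA_real_)
  sum(xc * (y - mean(y))) / sxx
}

# Deterministic stratified, patient-grouped fold assignment. Returns an
# integer fold id per patient. Stratification is by outcome label so every
# fold carries approximately the cohort death rate.
assign_folds <- function(patient_id, label, n_folds, seed) {
  stopifnot(length(patient_id) == length(label))
  fold <- integer(length(patient_id))
  withr::with_seed(seed, {
    for (lv in unique(label)) {
      idx <- which(label == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Convert a count of 5-minute median values to monitoring hours
#'
#' One value per 5-minute grid slot, so `n` values correspond to
#' `n * resolution_min / 60` hours of monitoring (e.g. 1,080 five-minute
#' medians are 90 h).
#'
#' @param n_values Number of grid values.
#' @param resolution_min Grid resolution in minutes (default 5).
#' @return Hours of monitoring covered, as a double.
#' @examples
#' monitoring_hours_from_counts(1080)
#' @export
monitoring_hours_from_counts <- function(n_values, resolution_min = 5) {
  stopifnot(is.numeric(n_values), n_values >= 0)
  n_values * resolution_min / 60
}
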