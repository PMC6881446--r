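## Static comparison model: logistic regression on IMPACT-style admission
## covariates (age, motor score, pupillary reactivity, hypoxia, hypotension,
## Marshall CT class, traumatic SAH, epidural mass, glucose, hemoglobin),
## refit on the cohort at hand.

IMPACT_PUPIL_LEVELS <- c("both", "one", "none")
IMPACT_MARSHALL_LEVELS <- c("DI_I", "DI_II", "DI_III", "DI_IV", "EML_NEML")

impact_frame <- function(baseline, labels) {
  check_columns(baseline, c("patient_id", "age", "motor", "pupils", "hypoxia",
                            "hypotension", "marshall", "tsah", "epidural",
                            "glucose", "hb"), "baseline table")
  bad_pupils <- setdiff(unique(baseline$pupils), IMPACT_PUPIL_LEVELS)
  if (length(bad_pupils)) {
    abort(sprintf("unknown pupil level(s): %s",
                  paste(bad_pupils, collapse = ", ")))
  }
  bad_marshall <- setdiff(unique(baseline$marshall), IMPACT_MARSHALL_LEVELS)
  if (length(bad_marshall)) {
    abort(sprintf("unknown Marshall CT level(s): %s",
                  paste(bad_marshall, collapse = ", ")))
  }
  df <- baseline |>
    dplyr::transmute(
      .data$patient_id,
      age = .data$age,
      motor = as.numeric(.data$motor),  # ordinal 1-6
      pupils = factor(.data$pupils, levels = IMPACT_PUPIL_LEVELS),
      hypoxia = as.logical(.data$hypoxia),
      hypotension = as.logical(.data$hypotension),
      marshall = factor(.data$marshall, levels = IMPACT_MARSHALL_LEVELS),
      tsah = as.logical(.data$tsah),
      epidural = as.logical(.data$epidural),
      glucose = .data$glucose,
      hb = .data$hb
    )
  dplyr::left_join(df, dplyr::select(labels, "patient_id", "label"),
                   by = "patient_id")
}

#' Fit the static IMPACT-style admission model
#'
#' Refits a logistic regression of 30-day mortality on the IMPACT admission
#' covariates of this cohort (one row per patient; coefficients are refit,
#' not the published IMPACT weights). The laboratory model (with admission
#' glucose and hemoglobin) scores every complete-case patient; patients with
#' missing glucose or hemoglobin fall back to the core covariate set rather
#' than being imputed or dropped.
#'
#' @param baseline Baseline tibble (see [censor_cohort()] for the dialect).
#' @param labels Tibble `patient_id`, `label`; defaults to deaths within 30
#'   days derived from `baseline$death_hour`.
#' @return An `icudyn_impact`: glm fits (`fit_lab`, `fit_core`), per-patient
#'   `risks` (`patient_id`, `risk`, `model_used`, `label`) and counts.
#' @export
fit_impact_model <- function(baseline, labels = NULL) {
  if (is.null(labels)) {
    check_columns(baseline, "death_hour", "baseline table")
    labels <- tibble::tibble(
      patient_id = baseline$patient_id,
      label = !is.na(baseline$death_hour) & baseline$death_hour <= 720)
  }
  df <- impact_frame(baseline, labels)
  if (length(unique(df$label)) < 2L) {
    abort("IMPACT model fitting needs both outcome classes")
  }
  core_rhs <- "age + motor + pupils + hypoxia + hypotension + marshall + tsah + epidural"
  complete_lab <- !is.na(df$glucose) & !is.na(df$hb)
  fit_lab <- stats::glm(
    stats::as.formula(paste("label ~", core_rhs, "+ glucose + hb")),
    family = stats::binomial(), data = df[complete_lab, , drop = FALSE])
  fit_core <- stats::glm(
    stats::as.formula(paste("label ~", core_rhs)),
    family = stats::binomial(), data = df)
  risk <- ifelse(complete_lab,
                 stats::predict(fit_lab, newdata = df, type = "response"),
                 stats::predict(fit_core, newdata = df, type = "response"))
  structure(
    list(fit_lab = fit_lab, fit_core = fit_core,
         risks = tibble::tibble(patient_id = df$patient_id, risk = risk,
                                model_used = ifelse(complete_lab, "lab", "core"),
                                label = df$label),
         n = nrow(df), n_fallback = sum(!complete_lab)),
    class = "icudyn_impact"
  )
}

#' @export
print.icudyn_impact <- function(x, ...) {
  cat(sprintf(
    "<icudyn_impact> %d patients (%d scored by the core fallback), AUC %.3f\n",
    x$n, x$n_fallback, auc(x$risks$risk, x$risks$label)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.icudyn_impact <- function(x, model = c("lab", "core"), ...) {
  model <- match.arg(model)
  fit <- if (model == "lab") x$fit_lab else x$fit_core
  s <- summary(fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @exportS3Method generics::glance
glance.icudyn_impact <- function(x, ...) {
  tibble::tibble(n = x$n, n_fallback = x$n_fallback,
                 auc = auc(x$risks$risk, x$risks$label),
                 deviance_lab = stats::deviance(x$fit_lab),
                 aic_lab = stats::AIC(x$fit_lab))
}

#' Binned calibration curve
#'
#' Observed mortality versus mean predicted risk in equal-frequency bins --
#' the tabular substrate of a calibration plot. With fewer distinct risk
#' values than requested bins, the bin count is reduced with a warning.
#'
#' @param risks Predicted probabilities.
#' @param labels Logical outcomes.
#' @param n_bins Number of equal-frequency bins (default 10).
#' @return Tibble `bin`, `n`, `mean_predicted`, `observed_rate`, `se`
#'   (binomial standard error of the observed rate).
#' @export
calibration_curve <- function(risks, labels, n_bins = 10) {
  stopifnot(length(risks) == length(labels))
  labels <- as.logical(labels)
  ok <- !is.na(risks) & !is.na(labels)
  risks <- risks[ok]; labels <- labels[ok]
  if (length(risks) < n_bins) {
    warn(sprintf("only %d predictions for %d bins; reducing bins",
                 length(risks), n_bins))
    n_bins <- max(1L, length(risks))
  }
  brk <- unique(stats::quantile(risks, seq(0, 1, length.out = n_bins + 1),
                                names = FALSE, type = 7))
  if (length(brk) - 1L < n_bins) {
    warn("tied risk values reduce the number of calibration bins")
  }
  bin <- cut(risks, breaks = brk, include.lowest = TRUE, labels = FALSE)
  tibble::tibble(risk = risks, label = labels, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_predicted = mean(.data$risk),
                     observed_rate = mean(.data$label),
                     .groups = "drop") |>
    dplyr::mutate(se = sqrt(.data$observed_rate * (1 - .data$observed_rate) /
                              .data$n)) |>
    dplyr::arrange(.data$bin)
}

#' Compare static admission-model decisions with the dynamic model
#'
#' For the patients the static IMPACT-style model predicts to die (risk
#' above the threshold), tallies how the dynamic model's last rolling
#' prediction classifies them -- the head-to-head view of whether dynamic
#' monitoring rescues static false positives.
#'
#' @param static_risks Tibble `patient_id`, `risk` (one row per patient), or
#'   an `icudyn_impact` object.
#' @param tracks Dynamic predictions from [predict_rolling()].
#' @param labels Tibble `patient_id`, `label`.
#' @param threshold Decision threshold for both models (default 0.5).
#' @return An `icudyn_comparison` list: `n_static_high`, `static_counts`
#'   (died / survived among static-high patients), `dynamic_counts`
#'   (dynamic classification of the same patients), `detail`.
#' @export
compare_static_vs_dynamic <- function(static_risks, tracks, labels,
                                      threshold = 0.5) {
  if (inherits(static_risks, "icudyn_impact")) {
    static_risks <- static_risks$risks[, c("patient_id", "risk")]
  }
  check_columns(static_risks, c("patient_id", "risk"), "static risks")
  check_columns(labels, c("patient_id", "label"), "labels")
  missing <- setdiff(labels$patient_id, static_risks$patient_id)
  if (length(missing)) {
    abort(sprintf("static risks missing for %d patient(s), e.g. %s",
                  length(missing), missing[1]))
  }
  dynamic <- classify_at_threshold(tracks, labels, threshold)
  joined <- static_risks |>
    dplyr::inner_join(dplyr::select(labels, "patient_id", "label"),
                      by = "patient_id") |>
    dplyr::left_join(dplyr::select(dynamic, "patient_id",
                                   dynamic_class = "classification",
                                   dynamic_last_risk = "last_risk"),
                     by = "patient_id")
  high <- joined[joined$risk > threshold, , drop = FALSE]
  structure(
    list(
      n_static_high = nrow(high),
      static_counts = tibble::tibble(
        died = sum(high$label), survived = sum(!high$label)),
      dynamic_counts = dplyr::count(high, .data$dynamic_class, name = "n"),
      detail = high,
      threshold = threshold
    ),
    class = "icudyn_comparison"
  )
}

#' @export
print.icudyn_comparison <- function(x, ...) {
  cat(sprintf(
    "<icudyn_comparison> %d patients above the %.0f%% static threshold: %d died, %d survived\n",
    x$n_static_high, 100 * x$threshold, x$static_counts$died,
    x$static_counts$survived))
  print(x$dynamic_counts)
  invisible(x)
}
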