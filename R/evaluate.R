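## Time-dependent, cross-validated discrimination and misclassification
## accounting.

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a randomly chosen non-survivor scores above a randomly
#' chosen survivor, with ties counted as one half. Undefined with a single
#' outcome class, in which case `NA` is returned.
#'
#' @param scores Numeric risk scores.
#' @param labels Logical (or 0/1) outcome, `TRUE` = died.
#' @return The AUC, or `NA` if only one class is present.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # midranks handle ties as 0.5
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated time-dependent AUC curve
#'
#' Repeated stratified patient-grouped cross-validation of the full training
#' pipeline: within every training fold the normalizer is refit, recursive
#' feature elimination rerun (unless `rfe = FALSE`) and the logistic model
#' refit; held-out risks are pooled per repetition and discrimination is
#' measured separately at each prediction time. The point estimate at each
#' time is the mean over repetitions, the 95% interval the 2.5/97.5
#' percentiles of the repetition-level AUCs. Repetition seeds derive
#' deterministically from the master seed (`seed + repetition`).
#'
#' @param features Raw feature matrix from [build_feature_matrix()].
#' @param n_folds Folds per repetition (default 5).
#' @param n_repeats Repetitions (default 20).
#' @param seed Master seed.
#' @param rfe Run feature elimination inside each fold (default `TRUE`).
#' @param lambda L2 strength.
#' @param rfe_folds Inner folds of the elimination.
#' @param keep_models Keep each fold's trained model (attribute `"models"`),
#'   mainly for leakage audits.
#' @return An `icudyn_auc_curve` tibble: `t_hours`, `auc`, `ci_low`,
#'   `ci_high`, `n_patients` (patients with a usable feature row at t),
#'   `n_deaths`. Held-out risks (`repetition`, `fold`, `patient_id`,
#'   `t_hours`, `risk`, `label`) are attached as attribute `"risks"`, fold
#'   assignments as `"folds"`.
#' @export
cross_validated_auc_curve <- function(features, n_folds = 5, n_repeats = 20,
                                      seed = 1L, rfe = TRUE, lambda = 1e-3,
                                      rfe_folds = 5, keep_models = FALSE) {
  variant <- attr(features, "variant")
  candidates <- attr(features, "candidates")
  if (is.null(candidates)) abort("`features` must come from build_feature_matrix()")
  pts <- dplyr::distinct(features, .data$patient_id, .data$label)
  if (length(unique(pts$label)) < 2L) {
    abort("cross-validation needs both outcome classes")
  }

  all_risks <- vector("list", n_repeats)
  all_folds <- vector("list", n_repeats)
  models <- if (keep_models) list() else NULL
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- seed + rep_i
    fold <- assign_folds(pts$patient_id, pts$label, n_folds, rep_seed)
    tries <- 0L
    while (tries < 50L) {
      bad <- vapply(seq_len(n_folds), function(f) {
        length(unique(pts$label[fold == f])) < 2L ||
          length(unique(pts$label[fold != f])) < 2L
      }, logical(1))
      if (!any(bad)) break
      tries <- tries + 1L
      warn(sprintf("repetition %d: fold without both classes, redrawing", rep_i))
      fold <- assign_folds(pts$patient_id, pts$label, n_folds,
                           rep_seed + 1000L * tries)
    }
    if (tries == 50L) abort("could not draw folds with both classes everywhere")
    fold_of <- stats::setNames(fold, pts$patient_id)
    all_folds[[rep_i]] <- tibble::tibble(
      repetition = rep_i, patient_id = pts$patient_id, fold = fold)

    rep_risks <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      train <- features[fold_of[features$patient_id] != f, , drop = FALSE]
      test <- features[fold_of[features$patient_id] == f, , drop = FALSE]
      attr(train, "variant") <- variant
      attr(train, "candidates") <- candidates
      attr(test, "variant") <- variant
      attr(test, "candidates") <- candidates
      model <- fit_dynamic_model(train, seed = rep_seed, rfe = rfe,
                                 lambda = lambda, rfe_folds = rfe_folds)
      if (keep_models) models[[sprintf("r%df%d", rep_i, f)]] <- model
      preds <- predict_rolling(model, test)
      rep_risks[[f]] <- dplyr::transmute(
        preds, repetition = rep_i, fold = f, .data$patient_id,
        .data$t_hours, .data$risk)
    }
    all_risks[[rep_i]] <- dplyr::bind_rows(rep_risks)
  }
  risks <- dplyr::bind_rows(all_risks) |>
    dplyr::left_join(pts, by = "patient_id")

  per_rep <- risks |>
    dplyr::group_by(.data$t_hours, .data$repetition) |>
    dplyr::summarise(auc = auc(.data$risk, .data$label), .groups = "drop")
  availability <- features |>
    dplyr::group_by(.data$t_hours) |>
    dplyr::summarise(n_patients = dplyr::n_distinct(.data$patient_id),
                     n_deaths = dplyr::n_distinct(
                       .data$patient_id[.data$label]),
                     .groups = "drop")
  curve <- per_rep |>
    dplyr::group_by(.data$t_hours) |>
    dplyr::summarise(
      ci_low = stats::quantile(.data$auc, 0.025, na.rm = TRUE, names = FALSE),
      ci_high = stats::quantile(.data$auc, 0.975, na.rm = TRUE, names = FALSE),
      auc = mean(.data$auc, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::relocate("auc", .after = "t_hours") |>
    dplyr::left_join(availability, by = "t_hours") |>
    dplyr::arrange(.data$t_hours)
  curve$auc[is.nan(curve$auc)] <- NA_real_
  attr(curve, "risks") <- risks
  attr(curve, "folds") <- dplyr::bind_rows(all_folds)
  if (keep_models) attr(curve, "models") <- models
  class(curve) <- c("icudyn_auc_curve", class(curve))
  curve
}

#' Misclassification accounting at the decision threshold
#'
#' Classifies every patient from the last rolling prediction (see
#' [classify_at_threshold()]) and tallies TP/FP/TN/FN plus unclassifiable
#' patients. False positives are additionally stratified the way a clinical
#' audit would look at them: by monitoring duration (within 48 h vs longer)
#' and by how far the last prediction exceeded the threshold (just above,
#' within 7 percentage points, vs clearly above).
#'
#' @param tracks Predictions from [predict_rolling()].
#' @param labels Tibble `patient_id`, `label`.
#' @param threshold Decision threshold (default 0.5).
#' @return An `icudyn_misclass` list: `counts` (classification, n), `detail`
#'   (per-patient classification) and `fp_detail` (false positives with
#'   `last_risk`, `risk_band`, `last_t_hours`, `duration_band`).
#' @export
misclassification_report <- function(tracks, labels, threshold = 0.5) {
  detail <- classify_at_threshold(tracks, labels, threshold)
  counts <- detail |>
    dplyr::count(.data$classification, name = "n") |>
    tidyr::complete(classification = c("TP", "FP", "TN", "FN",
                                       "unclassifiable"),
                    fill = list(n = 0L))
  fp <- detail[detail$classification == "FP", , drop = FALSE]
  fp_detail <- fp |>
    dplyr::mutate(
      risk_band = ifelse(.data$last_risk <= threshold + 0.07,
                         sprintf("%.0f-%.0f%%", 100 * threshold,
                                 100 * (threshold + 0.07)),
                         sprintf(">%.0f%%", 100 * (threshold + 0.07))),
      duration_band = ifelse(.data$last_t_hours <= 48,
                             "monitored 24-48 h", "monitored > 48 h")
    ) |>
    dplyr::select("patient_id", "last_risk", "risk_band", "last_t_hours",
                  "duration_band")
  structure(list(counts = counts, detail = detail, fp_detail = fp_detail,
                 threshold = threshold),
            class = "icudyn_misclass")
}

#' @export
print.icudyn_misclass <- function(x, ...) {
  n <- stats::setNames(x$counts$n, x$counts$classification)
  cat(sprintf(
    "<icudyn_misclass> threshold %.0f%%: TP %d, FP %d, TN %d, FN %d, unclassifiable %d\n",
    100 * x$threshold, n[["TP"]], n[["FP"]], n[["TN"]], n[["FN"]],
    n[["unclassifiable"]]))
  invisible(x)
}

#' Risk distributions over time by outcome group
#'
#' Kernel-free summaries of the predicted-risk distributions at each
#' prediction time, separately for survivors and non-survivors: group size,
#' mean and the nine deciles. Sufficient to render the violin-style view of
#' how the two groups separate over monitoring time.
#'
#' @param tracks Predictions from [predict_rolling()].
#' @param labels Tibble `patient_id`, `label`.
#' @return Tibble `t_hours`, `died`, `n`, `mean_risk`, `q10` ... `q90`.
#' @export
risk_distribution_over_time <- function(tracks, labels) {
  check_columns(labels, c("patient_id", "label"), "labels")
  probs <- seq(0.1, 0.9, by = 0.1)
  tracks |>
    dplyr::inner_join(dplyr::select(labels, "patient_id", "label"),
                      by = "patient_id") |>
    dplyr::group_by(.data$t_hours, died = .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_risk = mean(.data$risk),
      tibble::as_tibble_row(stats::setNames(
        as.list(stats::quantile(.data$risk, probs, names = FALSE, type = 7)),
        sprintf("q%d", round(100 * probs)))),
      .groups = "drop") |>
    dplyr::arrange(.data$t_hours, .data$died)
}
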