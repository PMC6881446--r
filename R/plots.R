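## ggplot2 views of the result objects.

#' Plot the time-dependent AUC curve
#'
#' Discrimination over monitoring time with the 95% repetition interval as a
#' ribbon.
#'
#' @param curve An `icudyn_auc_curve` from [cross_validated_auc_curve()].
#' @return A ggplot object.
#' @export
plot_auc_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$t_hours, y = .data$auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(breaks = unique(curve$t_hours)) +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::labs(x = "Hours from admission", y = "AUC (30-day mortality)",
                  title = "Time-dependent cross-validated discrimination") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.icudyn_auc_curve <- function(object, ...) plot_auc_curve(object)

#' Violin view of predicted risks over time by outcome
#'
#' @param tracks Predictions from [predict_rolling()].
#' @param labels Tibble `patient_id`, `label`.
#' @return A ggplot object.
#' @export
plot_risk_distribution <- function(tracks, labels) {
  dat <- dplyr::inner_join(tracks,
                           dplyr::select(labels, "patient_id", "label"),
                           by = "patient_id") |>
    dplyr::mutate(outcome = ifelse(.data$label, "died", "survived"))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$t_hours), y = .data$risk,
                                    fill = .data$outcome)) +
    ggplot2::geom_violin(scale = "width", alpha = 0.7,
                         position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::scale_fill_manual(values = c(died = "#4477aa",
                                          survived = "#ee8833")) +
    ggplot2::labs(x = "Hours from admission",
                  y = "Predicted 30-day mortality risk", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Calibration plot of a static model
#'
#' @param calibration Tibble from [calibration_curve()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(calibration) {
  ggplot2::ggplot(calibration,
                  ggplot2::aes(x = .data$mean_predicted,
                               y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$observed_rate - 1.96 * .data$se),
      ymax = pmin(1, .data$observed_rate + 1.96 * .data$se))) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed mortality") +
    ggplot2::theme_minimal()
}

#' Per-patient risk track with feature contributions
#'
#' The single-patient view: predicted risk over time on top of a tile map of
#' the signed per-feature contributions (coefficient x normalized value)
#' driving each prediction.
#'
#' @param tracks Predictions from [predict_rolling()].
#' @param patient One `patient_id` present in `tracks`.
#' @return A ggplot object (contribution tiles, risk overlaid as a line on a
#'   secondary scale).
#' @export
plot_risk_track <- function(tracks, patient) {
  one <- tracks[tracks$patient_id == patient, , drop = FALSE]
  if (nrow(one) == 0L) abort(sprintf("no predictions for patient '%s'", patient))
  contrib <- one |>
    tidyr::pivot_longer(dplyr::starts_with("contrib_"),
                        names_to = "feature", values_to = "contribution") |>
    dplyr::mutate(feature = sub("^contrib_", "", .data$feature))
  n_feat <- dplyr::n_distinct(contrib$feature)
  ggplot2::ggplot(contrib,
                  ggplot2::aes(x = factor(.data$t_hours), y = .data$feature)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$contribution)) +
    ggplot2::scale_fill_gradient2(low = "#4477aa", mid = "white",
                                  high = "#cc3311", midpoint = 0) +
    ggplot2::geom_line(ggplot2::aes(x = as.numeric(factor(.data$t_hours)),
                                    y = 0.5 + .data$risk * n_feat,
                                    group = 1),
                       colour = "#cc3311", linewidth = 1) +
    ggplot2::labs(x = "Hours from admission", y = NULL,
                  fill = "Contribution",
                  title = sprintf("Risk track for %s (line: risk, 0-1)",
                                  patient)) +
    ggplot2::theme_minimal()
}
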