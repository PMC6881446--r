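## Dynamic feature engineering: rolling-window derived series over the
## 5-minute grid, and begin/end/coef/last aspects evaluated at each
## prediction time.

# signal abbreviation <-> grid channel
SIGNAL_CHANNEL <- c(icp = "ICP", map = "MAP", cpp = "CPP",
                    mr = "GCS_M", er = "GCS_E")
# rolling window length in minutes: 4 h for the continuous pressures,
# 24 h for the sparsely observed GCS components
signal_window_min <- function(signal) {
  ifelse(signal %in% c("icp", "map", "cpp"), 240L, 1440L)
}

# minutes: begin aspect spans the first 24 h of monitoring, end/last aspects
# the trailing 8 h before a prediction
BEGIN_SPAN_MIN <- 1440L
END_SPAN_MIN <- 480L

#' Summary statistic of one rolling window
#'
#' The statistics behind the dynamic features: `mean`, `min`, `max`, `var`
#' (population variance), `q90`/`q10` (linearly interpolated percentiles),
#' `diff` (mean of consecutive signed differences, needing at least two
#' values), and threshold-exceedance fractions `ht20`/`lt10` (share of values
#' above 20 / below 10 mmHg, for ICP) and `ht120` (share above 120 mmHg, for
#' MAP). An empty window yields `NA` (a gap), never zero.
#'
#' @param x Numeric values of one window, in time order.
#' @param statistic One of `"mean"`, `"diff"`, `"var"`, `"q90"`, `"q10"`,
#'   `"min"`, `"max"`, `"ht20"`, `"lt10"`, `"ht120"`.
#' @return A single number, or `NA` for an empty window (or a single-value
#'   window for `diff`).
#' @examples
#' window_stat(c(2, 4, 6), "diff")           # 2
#' window_stat(c(15, 25, 25, 15), "ht20")    # 0.5
#' @export
window_stat <- function(x, statistic) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  switch(statistic,
    mean = mean(x),
    min = min(x),
    max = max(x),
    var = pop_var(x),
    q90 = stats::quantile(x, 0.9, names = FALSE, type = 7),
    q10 = stats::quantile(x, 0.1, names = FALSE, type = 7),
    diff = if (length(x) < 2L) NA_real_ else mean(diff(x)),
    ht20 = mean(x > 20),
    lt10 = mean(x < 10),
    ht120 = mean(x > 120),
    abort(sprintf("unknown statistic '%s'", statistic))
  )
}

# Statistics each signal's derived series needs, given the enumerated
# feature scheme.
signal_statistics <- function(signal) {
  switch(signal,
    icp = c("mean", "diff", "var", "q90", "q10", "min", "max", "ht20", "lt10"),
    map = c("mean", "diff", "var", "q90", "q10", "min", "max", "ht120"),
    cpp = c("mean", "diff", "var", "q90", "q10", "min", "max"),
    mr = ,
    er = c("mean", "var", "min", "max")
  )
}

# Window id for grid times: windows are anchored at the patient's monitoring
# start with step equal to the window length; window w covers
# (start + (w-1)*wl, start + w*wl], except that the point exactly at the
# monitoring start belongs to window 1.
window_index <- function(t_grid, start_min, window_min) {
  pmax(1L, as.integer(ceiling((t_grid - start_min) / window_min)))
}

#' Build the derived rolling-window series for one statistic
#'
#' Tiles the monitoring period of each patient/channel with consecutive
#' windows (4 h for ICP/MAP/CPP, 24 h for GCS components, anchored at the
#' patient's monitoring start) and computes `statistic` per window. Windows
#' without any contributing grid point produce no series point -- the gap is
#' preserved, never imputed.
#'
#' @param grid Gridded tibble (`patient_id`, `channel`, `t_grid`, `value`).
#' @param statistic A [window_stat()] statistic name.
#' @param window_hours Optional window length override in hours; by default
#'   4 h for ICP/MAP/CPP and 24 h for GCS channels.
#' @return Tibble `patient_id`, `channel`, `statistic`, `window_end_min`,
#'   `value`.
#' @export
build_derived_series <- function(grid, statistic, window_hours = NULL) {
  check_columns(grid, c("patient_id", "channel", "t_grid", "value"),
                "gridded vitals")
  starts <- grid |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(start_min = min(.data$t_grid), .groups = "drop")
  g <- dplyr::left_join(grid, starts, by = "patient_id")
  wl <- if (is.null(window_hours)) {
    sig <- names(SIGNAL_CHANNEL)[match(g$channel, SIGNAL_CHANNEL)]
    signal_window_min(sig)
  } else {
    rep(as.integer(window_hours * 60), nrow(g))
  }
  g$window <- window_index(g$t_grid, g$start_min, wl)
  g$window_end_min <- g$start_min + g$window * wl
  g |>
    dplyr::arrange(.data$patient_id, .data$channel, .data$t_grid) |>
    dplyr::group_by(.data$patient_id, .data$channel, .data$window_end_min) |>
    dplyr::summarise(value = window_stat(.data$value, statistic),
                     .groups = "drop") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(statistic = statistic, .after = "channel")
}

#' Linear trend of a derived series up to a prediction time
#'
#' Ordinary least-squares slope of the derived series values against window
#' end time (in hours), using every series point at or before `up_to_min`.
#' This is the `coef` feature aspect: the slope from the start of the derived
#' series up to the prediction time.
#'
#' @param series Tibble with `window_end_min` and `value` (one
#'   patient/channel/statistic).
#' @param up_to_min Prediction time in minutes from admission.
#' @return The slope in units per hour, or `NA` with fewer than two points.
#' @export
trend_coef <- function(series, up_to_min) {
  check_columns(series, c("window_end_min", "value"), "derived series")
  pts <- series[series$window_end_min <= up_to_min, , drop = FALSE]
  ols_slope(pts$window_end_min / 60, pts$value)
}

#' Enumerate the candidate dynamic feature scheme
#'
#' The candidate features the recursive elimination chooses from: for each
#' continuous signal (icp, map, cpp) the statistics mean/diff/var/q90/q10
#' crossed with the aspects begin (first 24 h of monitoring), end (trailing
#' 8 h) and coef (trend up to the prediction), plus last-window min and max
#' (17 per signal); plus the threshold-exceedance features `icp_ht20`,
#' `icp_lt10` and `map_ht120` -- 54 in total. The GCS variant adds, per
#' motor/eye component, mean and var crossed with begin/end/coef plus
#' min/max crossed with begin/end (10 per component) -- 74 in total. The age
#' category enters the models separately and is not part of this enumeration.
#' Mean-aspect names abbreviate to `signal_aspect` (`icp_end`, `map_coef`);
#' last-window extremes to `signal_statistic` (`icp_min`).
#'
#' @param variant `"ICP-MAP-CPP"` or `"ICP-MAP-CPP-GCS"`.
#' @return Tibble `name`, `signal`, `statistic`, `aspect` with unique names.
#' @examples
#' nrow(enumerate_features("ICP-MAP-CPP"))      # 54
#' nrow(enumerate_features("ICP-MAP-CPP-GCS"))  # 74
#' @export
enumerate_features <- function(variant = c("ICP-MAP-CPP", "ICP-MAP-CPP-GCS")) {
  variant <- match.arg(variant)
  cont <- dplyr::bind_rows(
    tidyr::expand_grid(signal = c("icp", "map", "cpp"),
                       statistic = c("mean", "diff", "var", "q90", "q10"),
                       aspect = c("begin", "end", "coef")),
    tidyr::expand_grid(signal = c("icp", "map", "cpp"),
                       statistic = c("min", "max"),
                       aspect = "last"),
    tibble::tibble(signal = c("icp", "icp", "map"),
                   statistic = c("ht20", "lt10", "ht120"),
                   aspect = "last")
  )
  spec <- cont
  if (variant == "ICP-MAP-CPP-GCS") {
    gcs <- dplyr::bind_rows(
      tidyr::expand_grid(signal = c("mr", "er"),
                         statistic = c("mean", "var"),
                         aspect = c("begin", "end", "coef")),
      tidyr::expand_grid(signal = c("mr", "er"),
                         statistic = c("min", "max"),
                         aspect = c("begin", "end"))
    )
    spec <- dplyr::bind_rows(spec, gcs)
  }
  spec$name <- ifelse(
    spec$statistic == "mean" & spec$aspect %in% c("begin", "end", "coef"),
    paste(spec$signal, spec$aspect, sep = "_"),
    ifelse(spec$aspect == "last",
           paste(spec$signal, spec$statistic, sep = "_"),
           paste(spec$signal, spec$statistic, spec$aspect, sep = "_"))
  )
  stopifnot(!anyDuplicated(spec$name))
  dplyr::select(spec, "name", "signal", "statistic", "aspect")
}

#' Dynamic features of the published final models
#'
#' The dynamic features retained by recursive elimination in the final
#' published algorithms, in relative importance order: 14 for the
#' ICP-MAP-CPP algorithm and 13 for the ICP-MAP-CPP-GCS algorithm, each used
#' together with the patient age category.
#'
#' @param variant `"ICP-MAP-CPP"` or `"ICP-MAP-CPP-GCS"`.
#' @param include_age Also include `"agecat"` at its importance rank.
#' @return Character vector of feature names.
#' @export
published_features <- function(variant = c("ICP-MAP-CPP", "ICP-MAP-CPP-GCS"),
                               include_age = FALSE) {
  variant <- match.arg(variant)
  feats <- if (variant == "ICP-MAP-CPP") {
    c("icp_end", "agecat", "map_q10_coef", "cpp_diff_begin", "map_q90_end",
      "map_coef", "icp_q90_end", "icp_diff_end", "icp_diff_coef",
      "map_var_begin", "icp_var_begin", "icp_diff_begin", "cpp_q10_end",
      "map_var_coef", "map_q10_begin")
  } else {
    c("er_min_end", "icp_end", "er_max_end", "agecat", "map_q10_coef",
      "er_end", "map_coef", "mr_end", "icp_diff_begin", "icp_diff_coef",
      "icp_var_begin", "er_var_end", "mr_coef", "er_max_begin")
  }
  if (include_age) feats else setdiff(feats, "agecat")
}

#' Encode age as an ordinal category in \[0, 1\]
#'
#' Five 15-year bands over the adult range: \[16, 30), \[30, 45), \[45, 60),
#' \[60, 75), \[75, Inf) map to 0, 0.25, 0.5, 0.75, 1.
#'
#' @param age Age in years; must be at least 16 (adult cohort).
#' @return Numeric vector in \[0, 1\].
#' @export
encode_agecat <- function(age) {
  if (any(is.na(age)) || any(age < 16)) {
    abort("`age` must be >= 16 years (adult cohort).")
  }
  band <- findInterval(age, c(16, 30, 45, 60, 75))
  (band - 1) / 4
}

# All derived series needed for a variant, long format.
derived_stats_table <- function(grid, variant) {
  enum <- enumerate_features(variant)
  needed <- unique(enum[, c("signal", "statistic")])
  starts <- grid |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(start_min = min(.data$t_grid), .groups = "drop")
  purrr::pmap_dfr(needed, function(signal, statistic) {
    ch <- SIGNAL_CHANNEL[[signal]]
    g <- grid[grid$channel == ch, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    g <- dplyr::left_join(g, starts, by = "patient_id")
    wl <- signal_window_min(signal)
    g$window_end_min <- g$start_min +
      window_index(g$t_grid, g$start_min, wl) * wl
    g |>
      dplyr::arrange(.data$patient_id, .data$t_grid) |>
      dplyr::group_by(.data$patient_id, .data$window_end_min) |>
      dplyr::summarise(value = window_stat(.data$value, statistic),
                       .groups = "drop") |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::mutate(signal = signal, statistic = statistic)
  })
}

# Aggregate derived points of one aspect window. Extremes aggregate with
# their own statistic; everything else averages.
aspect_agg <- function(value, statistic) {
  if (length(value) == 0L) return(NA_real_)
  if (statistic[1] == "min") min(value)
  else if (statistic[1] == "max") max(value)
  else mean(value)
}

#' Build the (patient x prediction-time) dynamic feature matrix
#'
#' Evaluates every enumerated candidate feature of the variant at each
#' scheduled prediction time: `begin` aspects aggregate the derived series
#' over the first 24 h of monitoring, `end` aspects over the trailing 8 h
#' before the prediction, `last` takes the most recent derived point in the
#' trailing 8 h, and `coef` is the OLS trend of the derived series up to the
#' prediction time. A row is emitted only when the patient's usable data
#' covers at least 24 h before the prediction time and the time does not
#' exceed the patient's usable end. Missing windows yield `NA` cells -- no
#' imputation. Values are raw (unnormalized); see [fit_normalizer()].
#'
#' @param censored An `icudyn_censored` cohort from [censor_cohort()].
#' @param variant `"ICP-MAP-CPP"` or `"ICP-MAP-CPP-GCS"`.
#' @param times_hours Prediction schedule in hours from admission; default
#'   24, 32, ..., 120.
#' @return Tibble with `patient_id`, `t_hours`, `label`, one column per
#'   candidate feature, and `agecat`. Attributes: `"variant"`,
#'   `"candidates"` (dynamic feature names).
#' @export
build_feature_matrix <- function(censored,
                                 variant = c("ICP-MAP-CPP", "ICP-MAP-CPP-GCS"),
                                 times_hours = seq(24, 120, by = 8)) {
  variant <- match.arg(variant)
  stopifnot(inherits(censored, "icudyn_censored"))
  enum <- enumerate_features(variant)
  d <- derived_stats_table(censored$grid, variant)
  pts <- censored$patients

  begin_agg <- d |>
    dplyr::left_join(
      dplyr::select(pts, "patient_id", "monitoring_start_min"),
      by = "patient_id") |>
    dplyr::filter(.data$window_end_min <=
                    .data$monitoring_start_min + BEGIN_SPAN_MIN) |>
    dplyr::group_by(.data$patient_id, .data$signal, .data$statistic) |>
    dplyr::summarise(value = aspect_agg(.data$value, .data$statistic),
                     .groups = "drop") |>
    dplyr::mutate(aspect = "begin")

  one_time <- function(T_min) {
    win <- d[d$window_end_min <= T_min &
               d$window_end_min > T_min - END_SPAN_MIN, , drop = FALSE]
    end_agg <- win |>
      dplyr::group_by(.data$patient_id, .data$signal, .data$statistic) |>
      dplyr::summarise(
        end = aspect_agg(.data$value, .data$statistic),
        last = if (length(.data$value)) {
          .data$value[which.max(.data$window_end_min)]
        } else NA_real_,
        .groups = "drop") |>
      tidyr::pivot_longer(c("end", "last"), names_to = "aspect",
                          values_to = "value")
    coef_agg <- d[d$window_end_min <= T_min, , drop = FALSE] |>
      dplyr::group_by(.data$patient_id, .data$signal, .data$statistic) |>
      dplyr::summarise(value = ols_slope(.data$window_end_min / 60,
                                         .data$value),
                       .groups = "drop") |>
      dplyr::mutate(aspect = "coef")
    dplyr::bind_rows(begin_agg, end_agg, coef_agg) |>
      dplyr::inner_join(enum, by = c("signal", "statistic", "aspect")) |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::transmute(.data$patient_id, t_min = T_min, .data$name,
                       .data$value)
  }

  long <- purrr::map_dfr(as.integer(times_hours * 60), one_time)
  wide <- long |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
  # guarantee every candidate column exists even if nowhere computable
  for (nm in setdiff(enum$name, names(wide))) wide[[nm]] <- NA_real_

  rows <- wide |>
    dplyr::left_join(
      dplyr::select(pts, "patient_id", "label", "monitoring_start_min",
                    "usable_end_min"),
      by = "patient_id") |>
    dplyr::filter(.data$t_min >= .data$monitoring_start_min + BEGIN_SPAN_MIN,
                  .data$t_min <= .data$usable_end_min) |>
    dplyr::left_join(
      dplyr::transmute(censored$baseline, .data$patient_id,
                       agecat = encode_agecat(.data$age)),
      by = "patient_id") |>
    dplyr::transmute(.data$patient_id, t_hours = .data$t_min / 60,
                     .data$label, .data$agecat,
                     dplyr::across(dplyr::all_of(enum$name))) |>
    dplyr::arrange(.data$patient_id, .data$t_hours)
  attr(rows, "variant") <- variant
  attr(rows, "candidates") <- enum$name
  rows
}

#' Fit a min-max normalizer on training feature rows
#'
#' Records per-feature minima and maxima from training data only, so the
#' mapping to \[0, 1\] never sees validation or test rows.
#'
#' @param features Feature matrix rows (training folds only).
#' @param columns Feature columns to normalize; defaults to the matrix's
#'   dynamic candidates (`agecat` is already encoded into \[0, 1\] and is
#'   left alone).
#' @return An `icudyn_normalizer` tibble (`feature`, `min`, `max`).
#' @export
fit_normalizer <- function(features, columns = NULL) {
  columns <- columns %||% attr(features, "candidates") %||%
    setdiff(names(features), c("patient_id", "t_hours", "label", "agecat"))
  check_columns(features, columns, "feature matrix")
  bounds <- purrr::map_dfr(columns, function(cn) {
    x <- features[[cn]]
    x <- x[!is.na(x)]
    tibble::tibble(feature = cn,
                   min = if (length(x)) min(x) else NA_real_,
                   max = if (length(x)) max(x) else NA_real_)
  })
  structure(bounds, class = c("icudyn_normalizer", class(bounds)))
}

#' Apply fitted min-max normalization
#'
#' Maps each feature to `(x - min) / (max - min)`. Degenerate features
#' (`max == min`) map to 0.5; out-of-range application values are clipped to
#' \[0, 1\]; `NA` cells stay `NA`.
#'
#' @param features Feature matrix rows.
#' @param normalizer An `icudyn_normalizer` from [fit_normalizer()].
#' @return `features` with normalized columns (attributes preserved).
#' @export
apply_normalizer <- function(features, normalizer) {
  if (!inherits(normalizer, "icudyn_normalizer")) {
    abort("`normalizer` must come from fit_normalizer(); refusing to apply unfitted bounds.")
  }
  out <- features
  for (i in seq_len(nrow(normalizer))) {
    cn <- normalizer$feature[i]
    if (!cn %in% names(out)) next
    lo <- normalizer$min[i]; hi <- normalizer$max[i]
    x <- out[[cn]]
    if (is.na(lo) || is.na(hi)) {
      out[[cn]] <- ifelse(is.na(x), NA_real_, 0.5)
    } else if (hi == lo) {
      out[[cn]] <- ifelse(is.na(x), NA_real_, 0.5)
    } else {
      out[[cn]] <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
    }
  }
  out
}
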