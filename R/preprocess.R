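#' Physiologic validity bounds for artifact filtering
#'
#' Values strictly outside these bounds are treated as measurement artifacts:
#' ICP outside \[0, 100\] mmHg, MAP outside \[20, 150\] mmHg. The bounds
#' themselves are valid values (strict inequalities). GCS channels and CPP
#' carry no bounds and pass through untouched.
#'
#' @return A tibble with columns `channel`, `lower`, `upper`.
#' @export
artifact_bounds <- function() {
  tibble::tibble(
    channel = c("ICP", "MAP"),
    lower = c(0, 20),
    upper = c(100, 150)
  )
}

#' Remove out-of-bounds measurement artifacts
#'
#' Drops rows whose value lies strictly outside the physiologic bounds for
#' their channel (see [artifact_bounds()]); all other channels are untouched.
#' Works on raw samples (`t_min`) and on gridded series (`t_grid`) alike, so
#' the same bounds can be applied both before and after median aggregation.
#' Idempotent.
#'
#' @param x Tibble with columns `channel`, `value` (plus any others).
#' @param bounds Bounds table, defaulting to [artifact_bounds()].
#' @return `x` without artifact rows; the number of removed rows per channel
#'   is attached as attribute `"removed"`.
#' @export
filter_artifacts <- function(x, bounds = artifact_bounds()) {
  check_columns(x, c("channel", "value"), "vitals data")
  x2 <- dplyr::left_join(x, bounds, by = "channel")
  bad <- !is.na(x2$lower) & (x2$value < x2$lower | x2$value > x2$upper)
  bad[is.na(bad)] <- FALSE
  removed <- dplyr::count(x[bad, , drop = FALSE], .data$channel,
                          name = "rows_filtered")
  out <- x[!bad, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Aggregate raw samples to a 5-minute median grid
#'
#' Each raw sample is assigned to its nearest 5-minute grid slot (ties at the
#' 2.5-minute boundary round up) and every occupied slot carries the median of
#' its contributing samples. Slots with no contributing sample are simply
#' absent -- gaps are never filled. Non-numeric values are rejected and
#' counted, not silently coerced to zero.
#'
#' @param vitals Tibble with columns `patient_id`, `t_min`, `channel`,
#'   `value`.
#' @param resolution_min Grid resolution in minutes (default 5).
#' @return Tibble `patient_id`, `channel`, `t_grid`, `value`, ordered by
#'   patient, channel, time. Per-channel accounting (`rows_in`,
#'   `rows_rejected`, `rows_gridded`) is attached as attribute `"counts"`.
#' @examples
#' raw <- tibble::tibble(patient_id = "a", t_min = c(63L, 64L, 66L),
#'                       channel = "ICP", value = c(10, 20, 30))
#' resample_to_grid(raw)  # one grid point at 65 min carrying the median, 20
#' @export
resample_to_grid <- function(vitals, resolution_min = 5) {
  check_columns(vitals, c("patient_id", "t_min", "channel", "value"),
                "raw vitals")
  val <- vitals$value
  if (!is.numeric(val)) {
    val <- suppressWarnings(as.numeric(val))
  }
  non_numeric <- is.na(val) & !is.na(vitals$value)
  if (any(non_numeric)) {
    inform(sprintf("resample_to_grid: rejected %d non-numeric value row(s)",
                   sum(non_numeric)))
  }
  rejected <- is.na(val)  # non-numeric or missing
  dat <- vitals[!rejected, c("patient_id", "t_min", "channel")]
  dat$value <- val[!rejected]
  grid <- dat |>
    dplyr::mutate(t_grid = round_half_up(.data$t_min, resolution_min)) |>
    dplyr::group_by(.data$patient_id, .data$channel, .data$t_grid) |>
    dplyr::summarise(value = stats::median(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$patient_id, .data$channel, .data$t_grid)
  counts <- vitals |>
    dplyr::mutate(.rej = rejected) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(rows_in = dplyr::n(), rows_rejected = sum(.data$.rej),
                     .groups = "drop") |>
    dplyr::mutate(rows_kept = .data$rows_in - .data$rows_rejected) |>
    dplyr::left_join(dplyr::count(grid, .data$channel, name = "rows_gridded"),
                     by = "channel")
  attr(grid, "counts") <- counts
  grid
}

#' Derive cerebral perfusion pressure on the grid
#'
#' CPP is the difference between MAP and ICP; a CPP grid point exists only
#' where the same patient has both a MAP and an ICP value at the same grid
#' time (gaps propagate). Both input channels should already be
#' artifact-filtered.
#'
#' @param grid Gridded tibble from [resample_to_grid()] containing `ICP` and
#'   `MAP` rows.
#' @return `grid` with `CPP` rows appended, ordered.
#' @export
derive_cpp <- function(grid) {
  check_columns(grid, c("patient_id", "channel", "t_grid", "value"),
                "gridded vitals")
  if (any(grid$channel == "CPP")) {
    warn("derive_cpp: existing CPP rows are replaced")
    grid <- grid[grid$channel != "CPP", , drop = FALSE]
  }
  icp <- grid[grid$channel == "ICP", c("patient_id", "t_grid", "value")]
  map <- grid[grid$channel == "MAP", c("patient_id", "t_grid", "value")]
  cpp <- dplyr::inner_join(map, icp, by = c("patient_id", "t_grid"),
                           suffix = c("_map", "_icp")) |>
    dplyr::transmute(.data$patient_id, channel = "CPP", .data$t_grid,
                     value = .data$value_map - .data$value_icp)
  dplyr::bind_rows(grid, cpp) |>
    dplyr::arrange(.data$patient_id, .data$channel, .data$t_grid)
}

#' Apply cohort inclusion and death-censoring rules
#'
#' Builds the analysis cohort from gridded vitals and the baseline table:
#' * patients dying within 36 h of admission are excluded;
#' * for deaths within 120 h, all data in the last 12 h before death are
#'   dropped (treatment-withdrawal guard), so the usable end is
#'   `death - 12 h`;
#' * patients whose (censored) ICP monitoring span is 24 h or less are
#'   excluded;
#' * the outcome label is death within 30 days of admission.
#'
#' @param grid Gridded, artifact-filtered vitals (CPP already derived).
#' @param baseline Baseline tibble with `patient_id`, `admission_time`
#'   (hours, normally 0) and `death_hour` (hours from admission, `NA` for
#'   survivors).
#' @param min_monitor_hours Minimum ICP monitoring span (exclusive bound),
#'   default 24.
#' @param min_death_hours Earliest death compatible with inclusion, default
#'   36 (deaths at or before this are excluded).
#' @param death_trunc_hours Deaths within this horizon have their final
#'   `death_gap_hours` of data dropped; default 120.
#' @param death_gap_hours Width of the pre-death exclusion window, default 12.
#' @param outcome_days Outcome horizon in days, default 30.
#' @return An `icudyn_censored` list: `grid` (truncated), `patients`
#'   (`patient_id`, `label`, `death_hour`, `monitoring_start_min`,
#'   `usable_end_min`, `icp_span_min`), `baseline` (included patients only)
#'   and `excluded` (`patient_id`, `reason`).
#' @export
censor_cohort <- function(grid, baseline,
                          min_monitor_hours = 24,
                          min_death_hours = 36,
                          death_trunc_hours = 120,
                          death_gap_hours = 12,
                          outcome_days = 30) {
  check_columns(baseline, c("patient_id", "admission_time", "death_hour"),
                "baseline table")
  if (any(!is.na(baseline$death_hour) &
          baseline$death_hour < baseline$admission_time)) {
    abort("death recorded before admission: data-integrity error",
          class = "icudyn_integrity_error")
  }
  b <- dplyr::select(baseline, "patient_id", "admission_time", "death_hour")
  died <- !is.na(b$death_hour)

  excluded <- tibble::tibble(patient_id = character(0), reason = character(0))
  early <- died & b$death_hour <= min_death_hours
  excluded <- dplyr::bind_rows(excluded, tibble::tibble(
    patient_id = b$patient_id[early], reason = "death within 36 h"))

  b2 <- b[!early, , drop = FALSE]
  b2$usable_end_min <- ifelse(
    !is.na(b2$death_hour) & b2$death_hour <= death_trunc_hours,
    (b2$death_hour - death_gap_hours) * 60, Inf)

  g <- dplyr::inner_join(grid,
                         dplyr::select(b2, "patient_id", "usable_end_min"),
                         by = "patient_id")
  g <- g[g$t_grid <= g$usable_end_min, , drop = FALSE]
  g$usable_end_min <- NULL

  span <- g |>
    dplyr::filter(.data$channel == "ICP") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(icp_span_min = max(.data$t_grid) - min(.data$t_grid),
                     .groups = "drop")
  ext <- g |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(monitoring_start_min = min(.data$t_grid),
                     monitoring_end_min = max(.data$t_grid), .groups = "drop")

  pts <- b2 |>
    dplyr::left_join(span, by = "patient_id") |>
    dplyr::left_join(ext, by = "patient_id")
  short <- is.na(pts$icp_span_min) |
    pts$icp_span_min <= min_monitor_hours * 60
  excluded <- dplyr::bind_rows(excluded, tibble::tibble(
    patient_id = pts$patient_id[short],
    reason = "ICP monitoring span of 24 h or less"))
  pts <- pts[!short, , drop = FALSE]

  pts$usable_end_min <- pmin(pts$usable_end_min, pts$monitoring_end_min)
  pts$label <- !is.na(pts$death_hour) &
    pts$death_hour <= pts$admission_time + outcome_days * 24
  patients <- dplyr::select(pts, "patient_id", "label", "death_hour",
                            "monitoring_start_min", "usable_end_min",
                            "icp_span_min")
  g <- g[g$patient_id %in% patients$patient_id, , drop = FALSE]
  structure(
    list(grid = g,
         patients = patients,
         baseline = baseline[baseline$patient_id %in% patients$patient_id, ,
                             drop = FALSE],
         excluded = excluded),
    class = "icudyn_censored"
  )
}

#' @export
print.icudyn_censored <- function(x, ...) {
  cat(sprintf(
    "<icudyn_censored> %d included patients (%d deaths), %d excluded, %d grid rows\n",
    nrow(x$patients), sum(x$patients$label), nrow(x$excluded), nrow(x$grid)))
  invisible(x)
}

#' Full preprocessing chain from raw vitals to a censored cohort
#'
#' Convenience wrapper: artifact-filter raw samples, aggregate to the
#' 5-minute median grid, filter again on the grid (same bounds), derive CPP
#' and apply the inclusion/censoring rules.
#'
#' @param vitals Raw long-format vitals tibble.
#' @param baseline Baseline tibble (see [censor_cohort()]).
#' @param ... Passed on to [censor_cohort()].
#' @return An `icudyn_censored` object; preprocessing row accounting is
#'   attached as attribute `"counts"`.
#' @export
preprocess_cohort <- function(vitals, baseline, ...) {
  raw <- filter_artifacts(vitals)
  filtered_raw <- attr(raw, "removed")
  grid <- resample_to_grid(raw)
  counts <- attr(grid, "counts")
  grid <- filter_artifacts(grid)
  filtered_grid <- attr(grid, "removed")
  grid <- derive_cpp(grid)
  censored <- censor_cohort(grid, baseline, ...)
  counts <- counts |>
    dplyr::left_join(
      dplyr::rename(filtered_raw, rows_filtered_raw = "rows_filtered"),
      by = "channel") |>
    dplyr::left_join(
      dplyr::rename(filtered_grid, rows_filtered_grid = "rows_filtered"),
      by = "channel") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("rows_"),
                                \(x) dplyr::coalesce(x, 0L)))
  attr(censored, "counts") <- counts
  censored
}
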