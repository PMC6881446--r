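## Orchestration: reproducible end-to-end runs with a provenance manifest.

#' Configuration of an end-to-end pipeline run
#'
#' Collects every knob of a run: input paths (or a generator config for a
#' simulated cohort), model variant, prediction schedule, decision threshold,
#' cross-validation settings and the master seed from which every source of
#' randomness (simulation, elimination folds, repetition folds) is derived.
#'
#' @param out_dir Output directory for run artifacts.
#' @param vitals_path,baseline_path Input CSVs (ignored when `simulate` is
#'   given).
#' @param simulate Optional [sim_config()]; when present the cohort is
#'   generated rather than read.
#' @param variant Model variant.
#' @param seed Master seed.
#' @param first_t_hours,step_hours,last_t_hours Prediction schedule; defaults
#'   24 h, 8 h, 120 h.
#' @param threshold Decision threshold.
#' @param cv_folds,cv_repeats Cross-validation settings for the evaluation
#'   stage; `cv_repeats = 0` skips cross-validated evaluation.
#' @param rfe Run recursive feature elimination.
#' @param lambda L2 strength of the logistic fits.
#' @return An `icudyn_run_config` list.
#' @export
run_config <- function(out_dir,
                       vitals_path = NULL, baseline_path = NULL,
                       simulate = NULL,
                       variant = c("ICP-MAP-CPP", "ICP-MAP-CPP-GCS"),
                       seed = 1L,
                       first_t_hours = 24, step_hours = 8, last_t_hours = 120,
                       threshold = 0.5,
                       cv_folds = 5, cv_repeats = 20,
                       rfe = TRUE, lambda = 1e-3) {
  variant <- match.arg(variant)
  if (first_t_hours < 24 || step_hours <= 0 || last_t_hours < first_t_hours) {
    abort("invalid prediction schedule", class = "icudyn_invalid_config")
  }
  if (is.null(simulate) && (is.null(vitals_path) || is.null(baseline_path))) {
    abort("either `simulate` or both input paths are required",
          class = "icudyn_invalid_config")
  }
  structure(
    list(out_dir = out_dir, vitals_path = vitals_path,
         baseline_path = baseline_path, simulate = simulate,
         variant = variant, seed = as.integer(seed),
         first_t_hours = first_t_hours, step_hours = step_hours,
         last_t_hours = last_t_hours, threshold = threshold,
         cv_folds = cv_folds, cv_repeats = cv_repeats,
         rfe = rfe, lambda = lambda),
    class = "icudyn_run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", name, conditionMessage(e)),
          class = "icudyn_stage_error")
  })
}

#' Run the full pipeline and write a provenance manifest
#'
#' Executes simulate (optional) -> preprocess -> featurize -> train ->
#' predict -> evaluate, writing every artifact under the configured output
#' directory: cohort CSVs, model JSON, predictions CSV, evaluation JSON and
#' `manifest.json` (config hash, seed, versions and row counts at each
#' stage). Runs with the same config and seed produce identical manifests
#' and outputs.
#'
#' @param config An [run_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "icudyn_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  times <- seq(config$first_t_hours, config$last_t_hours,
               by = config$step_hours)

  cohort <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      cohort <- simulate_cohort(sim)
      write_cohort(cohort,
                   file.path(config$out_dir, "vitals.csv"),
                   file.path(config$out_dir, "baseline.csv"),
                   file.path(config$out_dir, "artifact_flags.csv"))
      cohort
    } else {
      for (p in c(config$vitals_path, config$baseline_path)) {
        if (!file.exists(p)) abort(sprintf("input file not found: '%s'", p))
      }
      read_cohort(config$vitals_path, config$baseline_path)
    }
  })

  censored <- stage("preprocess", preprocess_cohort(cohort$vitals,
                                                    cohort$baseline))
  features <- stage("featurize",
                    build_feature_matrix(censored, config$variant, times))
  model <- stage("train", fit_dynamic_model(
    features, seed = config$seed, rfe = config$rfe, lambda = config$lambda))
  stage("train", write_model(model, file.path(config$out_dir, "model.json")))

  tracks <- stage("predict", predict_rolling(model, features))
  stage("predict", readr::write_csv(
    tracks, file.path(config$out_dir, "predictions.csv")))

  evaluation <- stage("evaluate", {
    mis <- misclassification_report(tracks, censored$patients,
                                    config$threshold)
    curve <- NULL
    if (config$cv_repeats > 0) {
      curve <- cross_validated_auc_curve(
        features, n_folds = config$cv_folds, n_repeats = config$cv_repeats,
        seed = config$seed, rfe = config$rfe, lambda = config$lambda)
      readr::write_csv(
        attr(curve, "risks"),
        file.path(config$out_dir, "heldout_risks.csv"))
    }
    payload <- list(
      misclassification = as.list(stats::setNames(mis$counts$n,
                                                  mis$counts$classification)),
      auc_curve = if (!is.null(curve)) {
        as.list(curve[, c("t_hours", "auc", "ci_low", "ci_high",
                          "n_patients")])
      }
    )
    write_json_file(payload, file.path(config$out_dir, "evaluation.json"))
    list(misclass = mis, curve = curve)
  })

  counts <- attr(censored, "counts")
  # the manifest captures the scientific configuration; filesystem locations
  # are deliberately left out so identical runs yield identical manifests
  sci <- unclass(config[setdiff(names(config),
                                c("simulate", "out_dir", "vitals_path",
                                  "baseline_path"))])
  manifest <- list(
    config = sci,
    sim_config = if (!is.null(config$simulate)) unclass(config$simulate),
    config_hash = rlang::hash(list(sci, unclass(config$simulate))),
    seed = config$seed,
    versions = list(icudyn = as.character(utils::packageVersion("icudyn")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    counts = list(
      vitals_rows = nrow(cohort$vitals),
      baseline_rows = nrow(cohort$baseline),
      preprocessing = as.list(stats::setNames(
        lapply(seq_len(nrow(counts)), function(i) as.list(counts[i, -1])),
        counts$channel)),
      included_patients = nrow(censored$patients),
      excluded_patients = nrow(censored$excluded),
      deaths = sum(censored$patients$label),
      feature_rows = nrow(features),
      model_features = length(model$features),
      prediction_rows = nrow(tracks)
    )
  )
  write_json_file(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(structure(
    list(manifest = manifest, censored = censored, features = features,
         model = model, tracks = tracks, evaluation = evaluation),
    class = "icudyn_run"))
}

#' Validate input files without mutating them
#'
#' Schema, dtype, range and referential checks on the vitals/baseline CSV
#' pair: required columns, known channels, non-negative integer timestamps,
#' numeric values, GCS component ranges, every vitals patient having a
#' baseline row, and deaths not preceding admission. Report-only.
#'
#' @param vitals_path,baseline_path CSV paths.
#' @return Tibble `check`, `n_violations`, `detail`; zero rows of violations
#'   means a clean pair.
#' @export
validate_inputs <- function(vitals_path, baseline_path) {
  for (p in c(vitals_path, baseline_path)) {
    if (!file.exists(p)) abort(sprintf("input file not found: '%s'", p))
  }
  vitals <- readr::read_csv(vitals_path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
  baseline <- readr::read_csv(baseline_path, show_col_types = FALSE)
  out <- list()
  add <- function(check, n, detail = "") {
    out[[length(out) + 1L]] <<- tibble::tibble(
      check = check, n_violations = as.integer(n), detail = detail)
  }
  need_v <- c("patient_id", "t_min", "channel", "value")
  miss <- setdiff(need_v, names(vitals))
  add("vitals columns", length(miss), paste(miss, collapse = ", "))
  if (length(miss) == 0L) {
    bad_ch <- !vitals$channel %in% VITALS_CHANNELS
    add("known channel", sum(bad_ch),
        paste(utils::head(unique(vitals$channel[bad_ch]), 3), collapse = ", "))
    t_num <- suppressWarnings(as.numeric(vitals$t_min))
    add("t_min non-negative integer",
        sum(is.na(t_num) | t_num < 0 | t_num != floor(t_num)))
    v_num <- suppressWarnings(as.numeric(vitals$value))
    add("numeric value", sum(is.na(v_num) & !is.na(vitals$value)))
    gcs_m <- vitals$channel == "GCS_M" & !is.na(v_num)
    add("GCS motor in 1-6", sum(gcs_m & (v_num < 1 | v_num > 6)))
    gcs_e <- vitals$channel == "GCS_E" & !is.na(v_num)
    add("GCS eye in 1-4", sum(gcs_e & (v_num < 1 | v_num > 4)))
    if ("patient_id" %in% names(baseline)) {
      orphans <- setdiff(unique(vitals$patient_id), baseline$patient_id)
      add("vitals patient has baseline row", length(orphans),
          paste(utils::head(orphans, 3), collapse = ", "))
    }
  }
  need_b <- c("patient_id", "age", "admission_time", "death_hour")
  miss_b <- setdiff(need_b, names(baseline))
  add("baseline columns", length(miss_b), paste(miss_b, collapse = ", "))
  if (length(miss_b) == 0L) {
    add("death not before admission",
        sum(!is.na(baseline$death_hour) &
              baseline$death_hour < baseline$admission_time))
    add("adult age", sum(is.na(baseline$age) | baseline$age < 16))
  }
  dplyr::bind_rows(out) |>
    dplyr::filter(.data$n_violations > 0L)
}
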