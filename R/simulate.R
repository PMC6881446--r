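#' Configuration for the synthetic ICU cohort generator
#'
#' Parameters describing the simulated cohort: size, 30-day mortality rate,
#' vital-sign trajectory means for survivors and non-survivors, monitoring
#' durations, observation sparsity and data-quality corruption (artifacts,
#' gaps). Defaults emulate an ICP-monitored TBI cohort: ~19% 30-day
#' mortality, mean ICP higher and rising in non-survivors (hence lower CPP)
#' while MAP is distributed identically in both groups, sparse GCS
#' assessments at sedation-pause tests, and monitoring lasting roughly 3-5
#' days.
#'
#' @param n_patients Number of patients to simulate.
#' @param mortality_rate Probability of death within 30 days.
#' @param seed Integer seed; identical config + seed gives bit-identical output.
#' @param monitoring_hours_mean,monitoring_hours_sd Normal mean/SD of the
#'   monitoring duration in hours, clamped to
#'   `[monitoring_hours_min, monitoring_hours_max]`.
#' @param monitoring_hours_min,monitoring_hours_max Clamp bounds (hours).
#' @param icp_survivor_mean Survivor mean ICP (mmHg), constant over time.
#' @param icp_nonsurvivor_mean_start Non-survivor mean ICP at admission (mmHg).
#' @param icp_nonsurvivor_drift_per_day Non-survivor ICP drift (mmHg/day),
#'   scaled by `effect_ramp`.
#' @param icp_between_sd Between-patient SD of the individual ICP level (mmHg).
#' @param icp_within_sd Stationary SD of the within-patient AR(1) noise (mmHg).
#' @param map_mean,map_sd MAP mean and within-patient AR(1) SD (mmHg), same in
#'   both outcome groups.
#' @param map_between_sd Between-patient SD of the individual MAP level (mmHg).
#' @param gcs_obs_interval_hours Interval between GCS assessments (wake-up
#'   tests), hours.
#' @param artifact_rate Per-sample probability that an ICP/MAP sample is
#'   replaced by an out-of-physiologic-bounds artifact value.
#' @param gap_rate Per-sample probability that an ICP/MAP sample is dropped.
#' @param min_death_hour,max_death_hour Support of non-survivor death times
#'   (hours from admission).
#' @param early_death_mass Fraction of deaths drawn below 36 h (uniform on
#'   `[min_death_hour, 36)`) to exercise the early-death exclusion rule;
#'   remaining deaths are uniform on `[36, max_death_hour]`.
#' @param effect_ramp Dimensionless factor scaling the time-growing
#'   survivor/non-survivor ICP divergence; 0 freezes the divergence at its
#'   admission value.
#' @param sample_interval_min Raw sampling interval in minutes (1-5).
#' @param ar_phi AR(1) autocorrelation of within-patient noise.
#' @return A `sim_config` list.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 300,
                       mortality_rate = 0.19,
                       seed = 1L,
                       monitoring_hours_mean = 96,
                       monitoring_hours_sd = 24,
                       monitoring_hours_min = 30,
                       monitoring_hours_max = 144,
                       icp_survivor_mean = 12,
                       icp_nonsurvivor_mean_start = 16,
                       icp_nonsurvivor_drift_per_day = 3,
                       icp_between_sd = 5,
                       icp_within_sd = 4,
                       map_mean = 85,
                       map_sd = 10,
                       map_between_sd = 6,
                       gcs_obs_interval_hours = 12,
                       artifact_rate = 0.02,
                       gap_rate = 0.05,
                       min_death_hour = 24,
                       max_death_hour = 720,
                       early_death_mass = 0.05,
                       effect_ramp = 1,
                       sample_interval_min = 5,
                       ar_phi = 0.9) {
  cfg <- as.list(environment())
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 1) {
    abort("`n_patients` must be a positive count.", class = "icudyn_invalid_config")
  }
  rates <- c(mortality_rate, artifact_rate, gap_rate, early_death_mass)
  if (any(rates < 0 | rates > 1)) {
    abort("All rates must lie in [0, 1].", class = "icudyn_invalid_config")
  }
  if (monitoring_hours_mean <= 24) {
    abort("`monitoring_hours_mean` must exceed 24 h.", class = "icudyn_invalid_config")
  }
  if (min_death_hour >= max_death_hour) {
    abort("`min_death_hour` must be below `max_death_hour`.",
          class = "icudyn_invalid_config")
  }
  if (sample_interval_min < 1 || sample_interval_min > 5) {
    abort("`sample_interval_min` must lie in [1, 5].", class = "icudyn_invalid_config")
  }
  if (ar_phi < 0 || ar_phi >= 1) {
    abort("`ar_phi` must lie in [0, 1).", class = "icudyn_invalid_config")
  }
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# AR(1) noise with stationary SD `sd` and autocorrelation `phi`.
ar1_noise <- function(n, phi, sd) {
  if (n == 0L) return(numeric(0))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# Marginal distributions of admission covariates by outcome group.
# Anchored to the typical case mix of an ICP-monitored TBI cohort (older
# non-survivors, worse pupils and larger mass lesions among non-survivors,
# matched hypoxia/hypotension rates).
baseline_params <- function(died) {
  if (died) {
    list(age_meanlog = log(55), age_sdlog = 0.30,
         male = 0.77,
         motor_prob = c(0.30, 0.14, 0.07, 0.16, 0.23, 0.10),
         pupils_prob = c(both = 0.72, one = 0.17, none = 0.11),
         hypoxia = 0.20, hypotension = 0.10,
         marshall_prob = c(DI_I = 0.00, DI_II = 0.15, DI_III = 0.23,
                           DI_IV = 0.04, EML_NEML = 0.58),
         tsah = 0.79, epidural = 0.05,
         glucose_meanlog = log(8.7), hb_mean = 127)
  } else {
    list(age_meanlog = log(44), age_sdlog = 0.35,
         male = 0.81,
         motor_prob = c(0.18, 0.10, 0.06, 0.18, 0.28, 0.20),
         pupils_prob = c(both = 0.81, one = 0.15, none = 0.04),
         hypoxia = 0.16, hypotension = 0.11,
         marshall_prob = c(DI_I = 0.02, DI_II = 0.30, DI_III = 0.17,
                           DI_IV = 0.04, EML_NEML = 0.47),
         tsah = 0.70, epidural = 0.11,
         glucose_meanlog = log(7.5), hb_mean = 131)
  }
}

simulate_baseline_one <- function(pid, died, death_hour) {
  p <- baseline_params(died)
  tibble::tibble(
    patient_id = pid,
    age = round(min(95, max(16, stats::rlnorm(1, p$age_meanlog, p$age_sdlog))), 1),
    male = stats::runif(1) < p$male,
    motor = sample(1:6, 1L, prob = p$motor_prob),
    pupils = sample(names(p$pupils_prob), 1L, prob = p$pupils_prob),
    hypoxia = stats::runif(1) < p$hypoxia,
    hypotension = stats::runif(1) < p$hypotension,
    marshall = sample(names(p$marshall_prob), 1L, prob = p$marshall_prob),
    tsah = stats::runif(1) < p$tsah,
    epidural = stats::runif(1) < p$epidural,
    glucose = if (stats::runif(1) < 0.01) NA_real_ else
      round(stats::rlnorm(1, p$glucose_meanlog, 0.25), 2),
    hb = if (stats::runif(1) < 0.005) NA_real_ else
      round(stats::rnorm(1, p$hb_mean, 17), 1),
    admission_time = 0,
    death_hour = death_hour
  )
}

simulate_vitals_one <- function(pid, died, death_hour, monitor_end_hour, cfg) {
  t_min <- seq(0L, as.integer(floor(monitor_end_hour * 60)),
               by = as.integer(cfg$sample_interval_min))
  n <- length(t_min)
  t_days <- t_min / 1440

  icp_level <- if (died) {
    stats::rnorm(1, cfg$icp_nonsurvivor_mean_start, cfg$icp_between_sd)
  } else {
    stats::rnorm(1, cfg$icp_survivor_mean, cfg$icp_between_sd)
  }
  icp_mu <- icp_level +
    if (died) cfg$icp_nonsurvivor_drift_per_day * cfg$effect_ramp * t_days else 0
  icp <- icp_mu + ar1_noise(n, cfg$ar_phi, cfg$icp_within_sd)
  # keep genuine signal inside the valid bounds; monitor-grade precision
  icp <- round(pmin(pmax(icp, 0), 100), 2)

  map_level <- stats::rnorm(1, cfg$map_mean, cfg$map_between_sd)
  map <- map_level + ar1_noise(n, cfg$ar_phi, cfg$map_sd)
  map <- round(pmin(pmax(map, 20), 150), 2)

  cont <- tibble::tibble(
    patient_id = pid,
    t_min = rep(t_min, 2L),
    channel = rep(c("ICP", "MAP"), each = n),
    value = c(icp, map)
  )
  # monitoring gaps, then artifact injection on the surviving samples
  keep <- stats::runif(nrow(cont)) >= cfg$gap_rate
  cont <- cont[keep, , drop = FALSE]
  art <- stats::runif(nrow(cont)) < cfg$artifact_rate
  if (any(art)) {
    k <- sum(art)
    hi <- stats::runif(k) < 0.5
    is_icp <- cont$channel[art] == "ICP"
    # ICP artifacts land strictly outside [0, 100]; MAP outside [20, 150]
    cont$value[art] <- round(ifelse(
      is_icp,
      ifelse(hi, stats::runif(k, 101, 180), stats::runif(k, -30, -1)),
      ifelse(hi, stats::runif(k, 151, 250), stats::runif(k, 1, 19))), 2)
  }
  cont$artifact <- art

  # sparse GCS observations at wake-up tests; integers within component range
  gcs_t <- seq(0, monitor_end_hour, by = cfg$gcs_obs_interval_hours) * 60
  gcs_t <- as.integer(gcs_t)
  m_base <- if (died) 3 else 5
  e_base <- if (died) 2 else 3
  pre_death <- died && !is.na(death_hour)
  declining <- if (pre_death) gcs_t / 60 > death_hour - 24 else
    rep(FALSE, length(gcs_t))
  motor <- pmin(6L, pmax(1L, as.integer(round(
    m_base - 2 * declining + stats::rnorm(length(gcs_t), 0, 0.7)))))
  eye <- pmin(4L, pmax(1L, as.integer(round(
    e_base - 1 * declining + stats::rnorm(length(gcs_t), 0, 0.6)))))
  gcs <- tibble::tibble(
    patient_id = pid,
    t_min = rep(gcs_t, 2L),
    channel = rep(c("GCS_M", "GCS_E"), each = length(gcs_t)),
    value = as.numeric(c(motor, eye)),
    artifact = FALSE
  )
  dplyr::bind_rows(cont, gcs)
}

#' Simulate a synthetic ICP-monitored TBI cohort
#'
#' Generates per-patient admission covariates and raw vital-sign samples with
#' the group structure a dynamic mortality model should be able to exploit:
#' non-survivors have higher and (for `effect_ramp > 0`) rising mean ICP,
#' identical MAP distribution, lower motor/eye scores declining before death,
#' sparse GCS observations, monitoring gaps and injected out-of-bounds
#' artifacts. Deterministic given the config (which embeds the seed).
#'
#' @param config A [sim_config()].
#' @return An `icudyn_cohort` list with elements `vitals` (tibble:
#'   `patient_id`, `t_min`, `channel`, `value`, `artifact` debug flag),
#'   `baseline` (one row per patient, IMPACT-style covariates plus
#'   `admission_time` and `death_hour`) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 5, seed = 1))
#' dplyr::count(cohort$vitals, channel)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().",
          class = "icudyn_invalid_config")
  }
  withr::with_seed(config$seed, {
    n <- config$n_patients
    pid <- sprintf("P%04d", seq_len(n))
    died <- stats::runif(n) < config$mortality_rate
    early <- stats::runif(n) < config$early_death_mass
    lo <- config$min_death_hour
    early_hi <- min(36, config$max_death_hour)
    death_hour <- round(ifelse(
      died,
      ifelse(early & early_hi > lo,
             stats::runif(n, lo, early_hi),
             stats::runif(n, max(36, lo), config$max_death_hour)),
      NA_real_
    ), 2)
    dur <- pmin(pmax(
      stats::rnorm(n, config$monitoring_hours_mean, config$monitoring_hours_sd),
      config$monitoring_hours_min), config$monitoring_hours_max)
    monitor_end <- ifelse(died & death_hour < dur, death_hour, dur)

    baseline <- purrr::map_dfr(seq_len(n), function(i) {
      simulate_baseline_one(pid[i], died[i], death_hour[i])
    })
    vitals <- purrr::map_dfr(seq_len(n), function(i) {
      simulate_vitals_one(pid[i], died[i], death_hour[i], monitor_end[i], config)
    })
    structure(
      list(vitals = vitals, baseline = baseline, config = config),
      class = "icudyn_cohort"
    )
  })
}

#' @export
print.icudyn_cohort <- function(x, ...) {
  cat(sprintf(
    "<icudyn_cohort> %d patients, %d vital-sign samples, %d deaths (%.1f%%)\n",
    nrow(x$baseline), nrow(x$vitals), sum(!is.na(x$baseline$death_hour)),
    100 * mean(!is.na(x$baseline$death_hour))
  ))
  invisible(x)
}

#' Write a synthetic cohort to long-format CSV files
#'
#' Writes the vitals table (`patient_id, t_min, channel, value`) and the
#' baseline table. The artifact debug flags are never part of the main vitals
#' file; pass `flags_path` to store them in a side file for audits of the
#' artifact filter.
#'
#' @param cohort An `icudyn_cohort` from [simulate_cohort()].
#' @param vitals_path,baseline_path Output CSV paths.
#' @param flags_path Optional side CSV for the per-sample artifact flags.
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(cohort, vitals_path, baseline_path, flags_path = NULL) {
  stopifnot(inherits(cohort, "icudyn_cohort") || is.list(cohort))
  safe_write <- function(df, path) {
    tryCatch(readr::write_csv(df, path),
             error = function(e) abort(sprintf(
               "failed to write '%s': %s", path, conditionMessage(e))))
  }
  vit <- dplyr::select(cohort$vitals, "patient_id", "t_min", "channel", "value")
  safe_write(vit, vitals_path)
  safe_write(cohort$baseline, baseline_path)
  if (!is.null(flags_path)) {
    safe_write(dplyr::select(cohort$vitals, "patient_id", "t_min",
                             "channel", "artifact"), flags_path)
  }
  invisible(c(vitals = vitals_path, baseline = baseline_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param vitals_path,baseline_path CSV paths in the [write_cohort()] dialect.
#' @return An `icudyn_cohort` (without artifact flags or generator config).
#' @export
read_cohort <- function(vitals_path, baseline_path) {
  for (p in c(vitals_path, baseline_path)) {
    if (!file.exists(p)) abort(sprintf("input file not found: '%s'", p))
  }
  vitals <- readr::read_csv(
    vitals_path, show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      t_min = readr::col_integer(),
      channel = readr::col_character(),
      value = readr::col_double()
    )
  )
  baseline <- readr::read_csv(
    baseline_path, show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      pupils = readr::col_character(),
      marshall = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  structure(list(vitals = vitals, baseline = baseline, config = NULL),
            class = "icudyn_cohort")
}
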