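# Shared fixtures, built once per test run and cached.

.icudyn_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .icudyn_cache)) {
    assign(key, force(expr), envir = .icudyn_cache)
  }
  get(key, envir = .icudyn_cache)
}

demo_cohort <- function() {
  cached("cohort", simulate_cohort(sim_config(n_patients = 100, seed = 420)))
}

demo_censored <- function() {
  cached("censored", {
    co <- demo_cohort()
    preprocess_cohort(co$vitals, co$baseline)
  })
}

demo_features <- function() {
  cached("features", build_feature_matrix(demo_censored(), "ICP-MAP-CPP"))
}

demo_model <- function() {
  cached("model", fit_dynamic_model(demo_features(), seed = 5, rfe = FALSE))
}

demo_tracks <- function() {
  cached("tracks", predict_rolling(demo_model(), demo_features()))
}

# Wrap a hand-built grid into the censored-cohort container feature building
# expects. Monitoring extent is taken from the grid itself.
make_censored <- function(grid, label = FALSE, age = 50) {
  pts <- grid |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(monitoring_start_min = min(t_grid),
                     usable_end_min = max(t_grid), .groups = "drop")
  pts$label <- rep_len(label, nrow(pts))
  pts$death_hour <- NA_real_
  pts$icp_span_min <- pts$usable_end_min - pts$monitoring_start_min
  baseline <- tibble::tibble(patient_id = pts$patient_id,
                             age = rep_len(age, nrow(pts)),
                             admission_time = 0, death_hour = NA_real_)
  structure(list(grid = grid, patients = pts, baseline = baseline,
                 excluded = tibble::tibble(patient_id = character(0),
                                           reason = character(0))),
            class = "icudyn_censored")
}

# A small feature tibble with the attributes fit_dynamic_model() expects,
# for model tests that plant their own signal.
synth_features <- function(df, candidates, variant = "ICP-MAP-CPP") {
  attr(df, "variant") <- variant
  attr(df, "candidates") <- candidates
  df
}

# Feature tibble with a planted 3-feature signal among pure noise columns.
planted_features <- function(seed, n = 200, n_noise = 20, beta = 4) {
  withr::with_seed(seed, {
    inf <- matrix(stats::runif(n * 3), ncol = 3,
                  dimnames = list(NULL, c("sig1", "sig2", "sig3")))
    noise <- matrix(stats::runif(n * n_noise), ncol = n_noise,
                    dimnames = list(NULL, sprintf("noise%02d", seq_len(n_noise))))
    eta <- beta * (inf[, 1] + inf[, 2] + inf[, 3]) - 1.5 * beta
    y <- stats::rbinom(n, 1, stats::plogis(eta)) == 1
    tibble::tibble(patient_id = sprintf("q%03d", seq_len(n)), label = y,
                   agecat = stats::runif(n)) |>
      dplyr::bind_cols(tibble::as_tibble(inf), tibble::as_tibble(noise))
  })
}

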