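test_that("generator is deterministic and validates its config", {
  cfg <- sim_config(n_patients = 8, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$vitals, b$vitals)
  expect_identical(a$baseline, b$baseline)

  expect_error(sim_config(n_patients = 0), class = "icudyn_invalid_config")
  expect_error(sim_config(n_patients = 10, mortality_rate = 1.2),
               class = "icudyn_invalid_config")
  expect_error(simulate_cohort(list(n_patients = 5)),
               class = "icudyn_invalid_config")
})

test_that("degenerate mortality rate produces no deaths", {
  co <- simulate_cohort(sim_config(n_patients = 12, mortality_rate = 0,
                                   seed = 3, monitoring_hours_mean = 36,
                                   monitoring_hours_sd = 2))
  expect_true(all(is.na(co$baseline$death_hour)))
})

test_that("observed mortality at n = 500 lies inside the binomial 99% interval", {
  co <- simulate_cohort(sim_config(n_patients = 500, seed = 99,
                                   monitoring_hours_mean = 30,
                                   monitoring_hours_sd = 1,
                                   monitoring_hours_min = 26))
  deaths <- sum(!is.na(co$baseline$death_hour))
  expect_gte(deaths, stats::qbinom(0.005, 500, 0.19))
  expect_lte(deaths, stats::qbinom(0.995, 500, 0.19))
})

test_that("patient-level invariants hold: death window, GCS ranges, artifact bounds", {
  co <- demo_cohort()
  cfg <- co$config
  dh <- co$baseline$death_hour
  expect_true(all(is.na(dh) |
                    (dh >= cfg$min_death_hour & dh <= cfg$max_death_hour)))
  gm <- co$vitals$value[co$vitals$channel == "GCS_M"]
  ge <- co$vitals$value[co$vitals$channel == "GCS_E"]
  expect_true(all(gm %in% 1:6))
  expect_true(all(ge %in% 1:4))

  # injected artifacts all fall strictly outside the validity bounds, and
  # nothing else does
  v <- co$vitals
  icp <- v[v$channel == "ICP", ]
  map <- v[v$channel == "MAP", ]
  expect_true(all(icp$value[icp$artifact] < 0 | icp$value[icp$artifact] > 100))
  expect_true(all(icp$value[!icp$artifact] >= 0 & icp$value[!icp$artifact] <= 100))
  expect_true(all(map$value[map$artifact] < 20 | map$value[map$artifact] > 150))
  expect_true(all(map$value[!map$artifact] >= 20 & map$value[!map$artifact] <= 150))
})

test_that("simulated ICP contrast matches the configured group difference", {
  co <- demo_cohort()
  cfg <- co$config
  icp <- co$vitals |>
    dplyr::filter(channel == "ICP", !artifact) |>
    dplyr::left_join(
      dplyr::transmute(co$baseline, patient_id,
                       died = !is.na(death_hour)),
      by = "patient_id")
  per_pat <- icp |>
    dplyr::group_by(patient_id, died) |>
    dplyr::summarise(
      obs = mean(value),
      expected = mean(ifelse(died,
                             cfg$icp_nonsurvivor_mean_start +
                               cfg$icp_nonsurvivor_drift_per_day *
                               cfg$effect_ramp * t_min / 1440,
                             cfg$icp_survivor_mean)),
      .groups = "drop")
  grp <- per_pat |>
    dplyr::group_by(died) |>
    dplyr::summarise(m_obs = mean(obs), m_exp = mean(expected),
                     se = stats::sd(obs) / sqrt(dplyr::n()),
                     .groups = "drop")
  contrast_obs <- grp$m_obs[grp$died] - grp$m_obs[!grp$died]
  contrast_exp <- grp$m_exp[grp$died] - grp$m_exp[!grp$died]
  se <- sqrt(sum(grp$se^2))
  expect_gt(contrast_obs, 0)
  expect_lt(abs(contrast_obs - contrast_exp), 3 * se)
})

test_that("group divergence grows from day 1 to day 5", {
  co <- demo_cohort()
  icp <- co$vitals |>
    dplyr::filter(channel == "ICP", !artifact) |>
    dplyr::left_join(
      dplyr::transmute(co$baseline, patient_id, died = !is.na(death_hour)),
      by = "patient_id") |>
    dplyr::mutate(day = ifelse(t_min < 1440, "day1",
                               ifelse(t_min >= 4 * 1440, "day5", NA)))
  sep <- icp |>
    dplyr::filter(!is.na(day)) |>
    dplyr::group_by(day, died) |>
    dplyr::summarise(m = mean(value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = died, values_from = m) |>
    dplyr::mutate(gap = `TRUE` - `FALSE`)
  expect_gt(sep$gap[sep$day == "day5"], sep$gap[sep$day == "day1"])
})

test_that("cohort files round-trip losslessly and conserve counts", {
  td <- withr::local_tempdir()
  vp <- file.path(td, "v.csv")
  bp <- file.path(td, "b.csv")

  # empty cohort: header-only files
  empty <- structure(list(
    vitals = tibble::tibble(patient_id = character(0), t_min = integer(0),
                            channel = character(0), value = double(0),
                            artifact = logical(0)),
    baseline = tibble::tibble(patient_id = character(0))), class = "icudyn_cohort")
  write_cohort(empty, vp, bp)
  expect_length(readLines(vp), 1L)
  expect_length(readLines(bp), 1L)

  # count conservation: 3 samples -> 3 vitals rows, 1 baseline row
  one <- structure(list(
    vitals = tibble::tibble(patient_id = "p1", t_min = c(0L, 5L, 10L),
                            channel = "ICP", value = c(10, 11, 12),
                            artifact = FALSE),
    baseline = tibble::tibble(patient_id = "p1", age = 40,
                              admission_time = 0, death_hour = NA_real_)),
    class = "icudyn_cohort")
  write_cohort(one, vp, bp)
  expect_length(readLines(vp), 4L)
  expect_length(readLines(bp), 2L)

  # write -> read -> write is byte-identical
  co <- simulate_cohort(sim_config(n_patients = 6, seed = 8,
                                   monitoring_hours_mean = 40,
                                   monitoring_hours_sd = 4))
  write_cohort(co, vp, bp)
  rt <- read_cohort(vp, bp)
  vp2 <- file.path(td, "v2.csv")
  bp2 <- file.path(td, "b2.csv")
  write_cohort(rt, vp2, bp2)
  expect_identical(readLines(vp), readLines(vp2))
  expect_identical(readLines(bp), readLines(bp2))

  expect_error(write_cohort(co, file.path(td, "nodir", "x.csv"), bp), "failed to write")
})
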