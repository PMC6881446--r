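raw_row <- function(t, value, channel = "ICP", pid = "p1") {
  tibble::tibble(patient_id = pid, t_min = t, channel = channel, value = value)
}

test_that("resampling takes bucket medians with half-up tie rounding", {
  # identity: single sample lands on its own slot
  g <- resample_to_grid(raw_row(65L, 12))
  expect_equal(g$t_grid, 65)
  expect_equal(g$value, 12)

  # samples at 63, 64, 66 all round to 65; median of 10, 20, 30 is 20
  g <- resample_to_grid(raw_row(c(63L, 64L, 66L), c(10, 20, 30)))
  expect_equal(nrow(g), 1L)
  expect_equal(g$t_grid, 65)
  expect_equal(g$value, 20)

  # tie at the x2.5 boundary rounds up
  g <- resample_to_grid(raw_row(c(62.5, 67.5), c(1, 2)))
  expect_equal(g$t_grid, c(65, 70))

  # no samples -> empty grid
  g <- resample_to_grid(raw_row(integer(0), double(0)))
  expect_equal(nrow(g), 0L)

  # even bucket: median interpolates between middle values
  g <- resample_to_grid(raw_row(c(64L, 66L), c(10, 30)))
  expect_equal(g$value, 20)
})

test_that("non-numeric values are rejected and counted, never coerced to zero", {
  raw <- tibble::tibble(patient_id = "p1", t_min = c(0L, 5L, 10L),
                        channel = "ICP", value = c("12", "oops", "14"))
  expect_message(g <- resample_to_grid(raw), "rejected 1 non-numeric")
  expect_equal(g$value, c(12, 14))
  counts <- attr(g, "counts")
  expect_equal(counts$rows_rejected, 1L)
  expect_equal(counts$rows_in, counts$rows_kept + counts$rows_rejected)
})

test_that("resampling an already-gridded series returns it unchanged", {
  grid <- demo_censored()$grid |> dplyr::filter(channel == "ICP")
  again <- resample_to_grid(dplyr::rename(grid, t_min = t_grid))
  expect_equal(again$t_grid, grid$t_grid)
  expect_equal(again$value, grid$value)
})

test_that("artifact bounds are strict and GCS passes through untouched", {
  g <- tibble::tibble(
    patient_id = "p1",
    channel = c("ICP", "ICP", "ICP", "ICP", "MAP", "MAP", "MAP", "GCS_M"),
    t_grid = seq(0, 35, by = 5),
    value = c(120, 100, 0, -1, 15, 20, 150, 6))
  out <- filter_artifacts(g)
  # ICP 120 and -1 removed, exactly 100 and 0 retained; MAP 15 removed,
  # 20 and 150 retained; GCS value 6 untouched
  expect_setequal(out$value, c(100, 0, 20, 150, 6))
  expect_equal(sum(attr(out, "removed")$rows_filtered), 3L)
  # idempotence
  again <- filter_artifacts(out)
  expect_equal(again$value, out$value)
  expect_equal(nrow(attr(again, "removed")), 0L)
})

test_that("the filter removes exactly the injected artifacts on synthetic data", {
  co <- demo_cohort()
  filtered <- filter_artifacts(co$vitals)
  expect_equal(nrow(filtered), sum(!co$vitals$artifact))
  expect_false(any(filtered$artifact))
  removed <- attr(filtered, "removed")
  expect_equal(sum(removed$rows_filtered), sum(co$vitals$artifact))
})

test_that("preprocessing conserves rows: in = kept + rejected + filtered", {
  co <- demo_cohort()
  cen <- demo_censored()
  counts <- attr(cen, "counts")
  raw_by_channel <- dplyr::count(co$vitals, channel)
  merged <- dplyr::left_join(raw_by_channel, counts, by = "channel")
  expect_equal(merged$n,
               merged$rows_kept + merged$rows_rejected +
                 merged$rows_filtered_raw)
})

test_that("CPP is MAP minus ICP where both exist, with gap propagation", {
  g <- tibble::tibble(
    patient_id = "p1",
    channel = c("MAP", "ICP", "MAP", "ICP", "MAP"),
    t_grid = c(0, 0, 5, 5, 10),
    value = c(80, 20, 70, 70, 90))
  out <- derive_cpp(g)
  cpp <- out[out$channel == "CPP", ]
  expect_equal(cpp$t_grid, c(0, 5))  # no ICP at t = 10 -> no CPP
  expect_equal(cpp$value, c(60, 0))
})

test_that("inclusion and censoring rules follow the cohort definition", {
  # four patients: early death (30 h), death at 100 h, short monitoring
  # survivor, and a full survivor
  mk <- function(pid, hours) {
    tibble::tibble(patient_id = pid, channel = "ICP",
                   t_grid = seq(0, hours * 60, by = 5),
                   value = 12)
  }
  grid <- dplyr::bind_rows(mk("early", 29), mk("d100", 98),
                           mk("short", 20), mk("surv", 100))
  baseline <- tibble::tibble(
    patient_id = c("early", "d100", "short", "surv"),
    admission_time = 0,
    death_hour = c(30, 100, NA, NA),
    age = 50)
  cen <- censor_cohort(grid, baseline)

  expect_setequal(cen$patients$patient_id, c("d100", "surv"))
  expect_setequal(cen$excluded$patient_id, c("early", "short"))
  expect_match(cen$excluded$reason[cen$excluded$patient_id == "early"],
               "36 h")

  # death at 100 h: data truncated at 88 h, labelled died
  d100 <- cen$grid[cen$grid$patient_id == "d100", ]
  expect_lte(max(d100$t_grid), 88 * 60)
  expect_true(cen$patients$label[cen$patients$patient_id == "d100"])
  expect_equal(cen$patients$usable_end_min[cen$patients$patient_id == "d100"],
               88 * 60)
  expect_false(cen$patients$label[cen$patients$patient_id == "surv"])

  # death beyond the 5-day horizon: no truncation
  baseline2 <- tibble::tibble(patient_id = "late", admission_time = 0,
                              death_hour = 200, age = 50)
  cen2 <- censor_cohort(mk("late", 100), baseline2)
  expect_equal(max(cen2$grid$t_grid), 100 * 60)
  expect_true(cen2$patients$label)

  # death after 30 days is a survivor label
  baseline3 <- tibble::tibble(patient_id = "d40", admission_time = 0,
                              death_hour = 31 * 24, age = 50)
  cen3 <- censor_cohort(mk("d40", 100), baseline3)
  expect_false(cen3$patients$label)

  expect_error(
    censor_cohort(mk("bad", 48),
                  tibble::tibble(patient_id = "bad", admission_time = 10,
                                 death_hour = 5, age = 50)),
    class = "icudyn_integrity_error")
})

test_that("no censored patient retains data within 12 h of death", {
  co <- demo_cohort()
  cen <- demo_censored()
  joined <- cen$grid |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(last = max(t_grid), .groups = "drop") |>
    dplyr::left_join(cen$patients[, c("patient_id", "death_hour")],
                     by = "patient_id")
  early_deaths <- joined[!is.na(joined$death_hour) &
                           joined$death_hour <= 120, ]
  expect_true(all(early_deaths$last <= (early_deaths$death_hour - 12) * 60))
})
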