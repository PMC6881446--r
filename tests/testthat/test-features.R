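test_that("window statistics match hand computations and the brute-force oracle", {
  expect_equal(window_stat(c(2, 4, 6), "diff"), 2)
  expect_equal(window_stat(c(7, 7, 7), "var"), 0)
  expect_equal(window_stat(c(7, 7, 7), "diff"), 0)
  expect_equal(window_stat(1:10, "q90"), oracle_quantile(1:10, 0.9))
  expect_equal(window_stat(c(15, 25, 25, 15), "ht20"), 0.5)
  expect_equal(window_stat(numeric(0), "mean"), NA_real_)
  expect_equal(window_stat(5, "diff"), NA_real_)
  expect_error(window_stat(1:3, "median"), "unknown statistic")

  stats_all <- c("mean", "diff", "var", "q90", "q10", "min", "max",
                 "ht20", "lt10", "ht120")
  for (seed in 1:20) {
    x <- withr::with_seed(seed, round(stats::runif(sample(1:12, 1), 0, 40), 1))
    for (st in stats_all) {
      expect_equal(window_stat(x, st), oracle_window_stat(x, st),
                   info = sprintf("seed %d stat %s", seed, st))
    }
  }
})

test_that("derived series tile the monitoring period and keep gaps", {
  # constant ICP over 24 h -> six 4-h windows, all equal to 12
  g <- tibble::tibble(patient_id = "p", channel = "ICP",
                      t_grid = seq(0, 1440, by = 5), value = 12)
  d <- build_derived_series(g, "mean")
  expect_equal(nrow(d), 6L)
  expect_equal(unique(d$value), 12)
  expect_equal(d$window_end_min, seq(240, 1440, by = 240))

  # a window with no grid points yields no derived point
  g2 <- g[g$t_grid < 240 | g$t_grid > 480, ]
  d2 <- build_derived_series(g2, "mean")
  expect_false(480 %in% d2$window_end_min)
  expect_equal(nrow(d2), 5L)

  # linear ramp: each window mean equals the line at the mean sampled time
  g3 <- tibble::tibble(patient_id = "p", channel = "ICP",
                       t_grid = seq(0, 2880, by = 5),
                       value = 10 + 20 * seq(0, 2880, by = 5) / 2880)
  d3 <- build_derived_series(g3, "mean")
  for (i in seq_len(nrow(d3))) {
    e <- d3$window_end_min[i]
    inside <- g3$t_grid > e - 240 & g3$t_grid <= e | (e == 240 & g3$t_grid == 0)
    expect_equal(d3$value[i], 10 + 20 * mean(g3$t_grid[inside]) / 2880)
  }
})

test_that("trend coefficients are OLS slopes per hour", {
  s <- tibble::tibble(window_end_min = c(0, 240, 480), value = c(1, 3, 5))
  expect_equal(trend_coef(s, 480), 0.5)
  expect_equal(trend_coef(s, 239), NA_real_)  # one point only
  s2 <- tibble::tibble(window_end_min = seq(240, 1200, by = 240), value = 4)
  expect_equal(trend_coef(s2, 1200), 0)
  s3 <- withr::with_seed(1, tibble::tibble(
    window_end_min = seq(240, 240 * 5, by = 240),
    value = stats::rnorm(5)))
  x <- s3$window_end_min / 60
  y <- s3$value
  expect_equal(trend_coef(s3, 99999),
               sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
})

test_that("the candidate enumeration has the canonical counts and names", {
  e1 <- enumerate_features("ICP-MAP-CPP")
  e2 <- enumerate_features("ICP-MAP-CPP-GCS")
  expect_equal(nrow(e1), 54L)
  expect_equal(nrow(e2), 74L)
  expect_false(anyDuplicated(e1$name) > 0)
  expect_false(anyDuplicated(e2$name) > 0)
  expect_false("agecat" %in% e2$name)
  # every published final-model feature appears among the candidates
  expect_true(all(published_features("ICP-MAP-CPP") %in% e1$name))
  expect_true(all(published_features("ICP-MAP-CPP-GCS") %in% e2$name))
  expect_length(published_features("ICP-MAP-CPP"), 14L)
  expect_length(published_features("ICP-MAP-CPP-GCS"), 13L)
  expect_error(enumerate_features("ICP-ONLY"))
})

test_that("age categories map 15-year bands onto {0, .25, .5, .75, 1}", {
  expect_equal(encode_agecat(16), 0)
  expect_equal(encode_agecat(29.9), 0)
  expect_equal(encode_agecat(30), 0.25)
  expect_equal(encode_agecat(48), 0.5)
  expect_equal(encode_agecat(74.9), 0.75)
  expect_equal(encode_agecat(90), 1)
  expect_error(encode_agecat(15), "16")
})

test_that("feature rows behave on simple deterministic grids", {
  t <- seq(0, 2880, by = 5)
  flat <- make_censored(derive_cpp(tibble::tibble(
    patient_id = "p", channel = rep(c("ICP", "MAP"), each = length(t)),
    t_grid = rep(t, 2), value = rep(c(12, 80), each = length(t)))))
  fm <- build_feature_matrix(flat, "ICP-MAP-CPP", times_hours = c(24, 48))
  expect_equal(nrow(fm), 2L)
  expect_equal(fm$icp_begin, c(12, 12))
  expect_equal(fm$icp_end, c(12, 12))
  expect_equal(fm$icp_coef, c(0, 0))
  expect_equal(fm$cpp_end, c(68, 68))
  expect_equal(fm$icp_var_end, c(0, 0))
  expect_equal(fm$icp_ht20, c(0, 0))

  # rising ICP 10 -> 30 over 48 h: positive trend, end above begin
  rising <- make_censored(derive_cpp(tibble::tibble(
    patient_id = "p", channel = rep(c("ICP", "MAP"), each = length(t)),
    t_grid = rep(t, 2),
    value = c(10 + 20 * t / 2880, rep(80, length(t))))))
  fr <- build_feature_matrix(rising, "ICP-MAP-CPP", times_hours = 48)
  expect_gt(fr$icp_coef, 0)
  expect_gt(fr$icp_end, fr$icp_begin)
  expect_lt(fr$cpp_coef, 0)  # CPP falls as ICP rises under constant MAP
})

test_that("feature rows equal brute-force recomputation on random grids", {
  for (seed in c(2, 7, 19)) {
    cen <- make_censored(random_small_grid(seed))
    for (variant in c("ICP-MAP-CPP", "ICP-MAP-CPP-GCS")) {
      fm <- build_feature_matrix(cen, variant, times_hours = c(24, 32, 48))
      enum <- enumerate_features(variant)
      for (i in seq_len(nrow(fm))) {
        expected <- oracle_feature_row(cen$grid, fm$t_hours[i] * 60, variant)
        got <- unlist(fm[i, enum$name])
        expect_equal(got, expected[names(got)], tolerance = 1e-10,
                     info = sprintf("seed %d variant %s t %g", seed, variant,
                                    fm$t_hours[i]))
      }
    }
  }
})

test_that("features are invariant to duplicated raw samples within a minute", {
  raw <- tibble::tibble(patient_id = "p",
                        t_min = rep(seq(0L, 2880L, by = 5L), 2),
                        channel = "ICP",
                        value = rep(10 + sin(seq(0, 2880, by = 5) / 100), 2))
  raw_dup <- dplyr::bind_rows(raw, raw[seq(1, nrow(raw), by = 3), ])
  g1 <- resample_to_grid(raw)
  g2 <- resample_to_grid(raw_dup)
  expect_equal(g1$value, g2$value)
})

test_that("feature rows at time t never use data after t", {
  cen <- demo_censored()
  ids <- utils::head(cen$patients$patient_id, 15)
  sub <- cen
  sub$grid <- cen$grid[cen$grid$patient_id %in% ids, ]
  sub$patients <- cen$patients[cen$patients$patient_id %in% ids, ]
  sub$baseline <- cen$baseline[cen$baseline$patient_id %in% ids, ]

  poisoned <- sub
  cutoff <- 48 * 60
  bad <- poisoned$grid$t_grid > cutoff
  poisoned$grid$value[bad & poisoned$grid$channel == "ICP"] <- 99
  poisoned$grid$value[bad & poisoned$grid$channel == "MAP"] <- 149

  fm_clean <- build_feature_matrix(sub, "ICP-MAP-CPP")
  fm_pois <- build_feature_matrix(poisoned, "ICP-MAP-CPP")
  keep <- fm_clean$t_hours <= 48
  expect_equal(fm_clean[keep, ], fm_pois[fm_pois$t_hours <= 48, ])
})

test_that("min-max normalization clips, handles degeneracy and round-trips", {
  df <- tibble::tibble(patient_id = "p", t_hours = 24, label = FALSE,
                       agecat = 0.5, a = c(0, 10, 5), b = 7)
  nb <- fit_normalizer(df, c("a", "b"))
  out <- apply_normalizer(df, nb)
  expect_equal(out$a, c(0, 1, 0.5))
  expect_equal(out$b, c(0.5, 0.5, 0.5))  # degenerate feature -> 0.5

  new <- tibble::tibble(a = c(12, -3, NA), b = 7)
  expect_equal(apply_normalizer(new, nb)$a, c(1, 0, NA))

  # round-trip on in-range data: denormalizing recovers the input
  x <- withr::with_seed(4, stats::runif(20, 2, 8))
  df2 <- tibble::tibble(a = x)
  nb2 <- fit_normalizer(df2, "a")
  z <- apply_normalizer(df2, nb2)$a
  expect_equal(z * (nb2$max - nb2$min) + nb2$min, x)

  expect_error(apply_normalizer(df, tibble::tibble(feature = "a", min = 0, max = 1)),
               "unfitted")
})
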