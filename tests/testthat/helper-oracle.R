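# Independent brute-force oracles for the windowing arithmetic. Written as
# plain loops and closed forms, deliberately sharing no code with the
# implementation.

oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L) return(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_window_stat <- function(x, statistic) {
  if (length(x) == 0L) return(NA_real_)
  if (statistic == "mean") return(sum(x) / length(x))
  if (statistic == "min") return(sort(x)[1])
  if (statistic == "max") return(sort(x)[length(x)])
  if (statistic == "var") {
    m <- sum(x) / length(x)
    return(sum((x - m)^2) / length(x))
  }
  if (statistic == "q90") return(oracle_quantile(x, 0.9))
  if (statistic == "q10") return(oracle_quantile(x, 0.1))
  if (statistic == "diff") {
    if (length(x) < 2L) return(NA_real_)
    d <- numeric(length(x) - 1L)
    for (i in seq_along(d)) d[i] <- x[i + 1L] - x[i]
    return(sum(d) / length(d))
  }
  if (statistic == "ht20") return(sum(x > 20) / length(x))
  if (statistic == "lt10") return(sum(x < 10) / length(x))
  if (statistic == "ht120") return(sum(x > 120) / length(x))
  stop("unknown statistic")
}

# Exhaustive pairwise AUC: every (death, survivor) pair scored 1 / 0.5 / 0.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Feature row at one prediction time by explicitly materializing every
# rolling window. lm() supplies the trend slopes.
oracle_feature_row <- function(grid_one, t_min, variant) {
  enum <- enumerate_features(variant)
  chan_of <- c(icp = "ICP", map = "MAP", cpp = "CPP",
               mr = "GCS_M", er = "GCS_E")
  start <- min(grid_one$t_grid)
  out <- stats::setNames(rep(NA_real_, nrow(enum)), enum$name)
  for (i in seq_len(nrow(enum))) {
    sig <- enum$signal[i]
    st <- enum$statistic[i]
    asp <- enum$aspect[i]
    wl <- if (sig %in% c("icp", "map", "cpp")) 240 else 1440
    gg <- grid_one[grid_one$channel == chan_of[[sig]], , drop = FALSE]
    gg <- gg[order(gg$t_grid), , drop = FALSE]
    if (nrow(gg) == 0L) next
    ends <- seq(start + wl, start + wl * ceiling((max(gg$t_grid) - start) / wl),
                by = wl)
    if (max(gg$t_grid) == start) ends <- start + wl
    pts_end <- numeric(0)
    pts_val <- numeric(0)
    for (e in ends) {
      inside <- (gg$t_grid > e - wl & gg$t_grid <= e) |
        (e == start + wl & gg$t_grid == start)
      v <- oracle_window_stat(gg$value[inside], st)
      if (!is.na(v)) {
        pts_end <- c(pts_end, e)
        pts_val <- c(pts_val, v)
      }
    }
    if (length(pts_end) == 0L) next
    agg <- function(v) {
      if (st == "min") min(v) else if (st == "max") max(v) else mean(v)
    }
    out[[enum$name[i]]] <- if (asp == "begin") {
      sel <- pts_val[pts_end <= start + 1440]
      if (length(sel)) agg(sel) else NA_real_
    } else if (asp == "end") {
      sel <- pts_val[pts_end > t_min - 480 & pts_end <= t_min]
      if (length(sel)) agg(sel) else NA_real_
    } else if (asp == "last") {
      keep <- pts_end > t_min - 480 & pts_end <= t_min
      if (any(keep)) pts_val[keep][which.max(pts_end[keep])] else NA_real_
    } else {  # coef
      keep <- pts_end <= t_min
      if (sum(keep) < 2L) NA_real_ else {
        unname(stats::coef(stats::lm(pts_val[keep] ~ I(pts_end[keep] / 60)))[2])
      }
    }
  }
  out
}

# Random small two-day grid with gaps, for oracle-equivalence sweeps.
random_small_grid <- function(seed, pid = "X1") {
  withr::with_seed(seed, {
    t <- seq(0, 48 * 60, by = 5)
    keep_icp <- stats::runif(length(t)) < 0.85
    keep_map <- stats::runif(length(t)) < 0.85
    icp <- tibble::tibble(patient_id = pid, channel = "ICP",
                          t_grid = t[keep_icp],
                          value = round(12 + cumsum(stats::rnorm(sum(keep_icp), 0, 0.8)), 2))
    map <- tibble::tibble(patient_id = pid, channel = "MAP",
                          t_grid = t[keep_map],
                          value = round(85 + cumsum(stats::rnorm(sum(keep_map), 0, 1.2)), 2))
    tg <- seq(0, 48 * 60, by = 720)
    gcs <- tibble::tibble(
      patient_id = pid,
      channel = rep(c("GCS_M", "GCS_E"), each = length(tg)),
      t_grid = rep(tg, 2L),
      value = c(sample(1:6, length(tg), replace = TRUE),
                sample(1:4, length(tg), replace = TRUE)))
    derive_cpp(dplyr::bind_rows(icp, map, gcs))
  })
}
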