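lognorm_events <- function(n, meanlog, sdlog, time_min = 0, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      event_id = seq_len(n),
      syfp = rlnorm(n, meanlog, sdlog),
      qd = rlnorm(n, meanlog, sdlog),
      time_min = time_min
    )
  })
}

test_that("gating against a control recovers known mixtures", {
  ctrl <- lognorm_events(5000, log(100), 0.5, seed = 2)
  # gating the control against itself leaves about 1 - quantile
  g <- gate_positive(ctrl, ctrl, "syfp", quantile = 0.995)
  expect_equal(nrow(g$events) / nrow(ctrl), 0.005, tolerance = 0.5)
  # a sample far above the control is fully gated
  hi <- dplyr::mutate(ctrl, syfp = syfp * 10 + max(ctrl$syfp))
  expect_equal(nrow(gate_positive(hi, ctrl)$events), nrow(ctrl))
  # well-separated mixture: gated fraction close to the transfected fraction
  ds <- generate_event_dataset(event_dataset_config(n_events = 10000, seed = 3))
  g2 <- gate_positive(ds$events[ds$events$time_min == 0, ], ds$control)
  p_hat <- nrow(g2$events) / 10000
  half <- qnorm(0.995) * sqrt(0.4 * 0.6 / 10000)
  expect_lt(abs(p_hat - 0.4), half + 0.005) # binomial CI + gate overlap slack
  expect_error(gate_positive(ctrl, ctrl[0, ]), "empty control")
})

test_that("quadrant counts partition the events and give labeled fractions", {
  ev <- tibble::tibble(
    syfp = c(10, 10, 1000, 1000, 1000, 1000),
    qd = c(5, 500, 5, 500, 500, 500)
  )
  q <- quadrant_statistics(ev, syfp_threshold = 100, qd_threshold = 100)
  expect_equal(q$I + q$II + q$III + q$IV, nrow(ev))
  expect_equal(q$II, 3)
  expect_equal(q$IV, 1)
  expect_equal(q$labeled_fraction, 0.75)
  # all events high in both channels
  allhi <- tibble::tibble(syfp = rep(1e3, 5), qd = rep(1e3, 5))
  expect_equal(quadrant_statistics(allhi, 100, 100)$labeled_fraction, 1)
  # no SYFP-high events: fraction undefined
  none <- tibble::tibble(syfp = rep(1, 5), qd = rep(1e3, 5))
  expect_true(is.na(quadrant_statistics(none, 100, 100)$labeled_fraction))
})

test_that("acid stripping lowers the labeled fraction of transfected events", {
  strip <- generate_event_dataset(
    event_dataset_config(n_events = 6000, acid_treated = TRUE, seed = 4)
  )
  keep <- generate_event_dataset(
    event_dataset_config(n_events = 6000, acid_treated = FALSE, seed = 4)
  )
  thr_s <- quantile(strip$control$syfp, 0.995)
  thr_q <- quantile(strip$control$qd, 0.995)
  q_strip <- quadrant_statistics(
    strip$events[strip$events$time_min == 0, ], thr_s, thr_q
  )
  q_keep <- quadrant_statistics(
    keep$events[keep$events$time_min == 0, ], thr_s, thr_q
  )
  expect_lt(q_strip$labeled_fraction, q_keep$labeled_fraction - 0.2)
})

test_that("geometric means obey their identities", {
  expect_equal(geometric_mean(c(1, 100)), 10)
  expect_equal(geometric_mean(4), 4)
  withr::with_seed(6, {
    x <- rlnorm(500, 2, 1)
  })
  expect_equal(geometric_mean(x), exp(mean(log(x))))
  # homogeneity and AM-GM
  expect_equal(geometric_mean(3.7 * x), 3.7 * geometric_mean(x))
  expect_lte(geometric_mean(x), mean(x))
  # zero policies
  expect_equal(geometric_mean(c(0, 1, 100), zero_policy = "exclude"), 10)
  expect_error(geometric_mean(c(0, 0), zero_policy = "exclude"), "no positive")
  # normalized series equals 1 at the reference time
  ev <- dplyr::bind_rows(
    lognorm_events(2000, log(50), 0.4, time_min = 0, seed = 7),
    lognorm_events(2000, log(150), 0.4, time_min = 20, seed = 8)
  )
  gs <- geometric_mean_series(ev)
  expect_equal(gs$normalized[gs$time_min == 0], 1)
  expect_gt(gs$normalized[gs$time_min == 20], 1)
})

test_that("marker placement realizes the requested tail", {
  # 100 distinct values: exactly 4 exceed the 96% threshold
  ref <- tibble::tibble(qd = as.numeric(1:100))
  thr <- place_marker(ref, tail_fraction = 0.04)
  expect_equal(sum(ref$qd > thr), 4)
  # large log-normal reference: realized tail within 0.5 points of 4%
  big <- lognorm_events(10000, log(200), 0.8, seed = 9)
  thr2 <- place_marker(big, tail_fraction = 0.04)
  expect_lt(abs(attr(thr2, "realized_tail") - 0.04), 0.005)
  expect_error(place_marker(big, tail_fraction = 0.6), "\\(0, 0.5\\)")
})

test_that("marker series normalizes to time zero and tracks upward shifts", {
  ev0 <- lognorm_events(4000, log(100), 0.6, time_min = 0, seed = 10)
  ev20 <- lognorm_events(4000, log(100), 0.6, time_min = 20, seed = 11)
  thr <- place_marker(ev0)
  null_series <- marker_series(dplyr::bind_rows(ev0, ev20), thr)
  expect_equal(null_series$normalized[null_series$time_min == 0], 1)
  # identical distributions: flat within sampling error (3 binomial SEs)
  p0 <- null_series$pct_above[null_series$time_min == 0] / 100
  se <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(
    abs(null_series$pct_above[null_series$time_min == 20] / 100 - p0), 3 * se
  )
  # progressively doubling the intensities never decreases the series
  shifted <- dplyr::bind_rows(
    ev0,
    dplyr::mutate(ev20, qd = qd * 2),
    dplyr::mutate(ev20, qd = qd * 4, time_min = 40)
  )
  ms <- marker_series(shifted, thr)
  expect_true(all(diff(ms$normalized) >= 0))
})

test_that("fold versus control is a guarded ratio", {
  # the published specific-binding example: 0.54 over 0.10 gives 5.4-fold
  expect_equal(fold_vs_control(0.54, 0.10), 5.4)
  expect_equal(fold_vs_control(0.2, 0.2), 1)
  expect_equal(fold_vs_control(0, 0.1), 0)
  expect_error(fold_vs_control(0.5, 0), "> 0")
})

test_that("event tables round-trip through CSV with channel mapping", {
  ev <- lognorm_events(50, log(100), 0.5, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  names(ev)[2:3] <- c("FL1", "FL2")
  write.csv(ev, path, row.names = FALSE)
  back <- read_event_table(path, channel_map = c(syfp = "FL1", qd = "FL2"))
  expect_equal(back$syfp, ev$FL1)
  expect_equal(back$qd, ev$FL2)
  expect_error(read_event_table(path), "missing channel")
})
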