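midnight <- as.POSIXct("2022-01-01 00:00:00", tz = "UTC")

stream_from_runs <- function(runs, rr_s = 1, start = midnight) {
  t <- unlist(lapply(runs, function(r) constant_run(r[1], r[2], rr_s)))
  beat_stream(t, rep("N", length(t)), recording_start = start,
              duration_s = max(t) + rr_s)
}

test_that("day/night coverage rule accumulates interval intersections", {
  # recording starts at midnight: 10:00-14:00 day block, 22:00-02:00 night block
  ok <- stream_from_runs(list(c(10, 14) * 3600, c(22, 26) * 3600))
  expect_true(check_monitoring_coverage(ok))
  day_only <- stream_from_runs(list(c(10, 14) * 3600))
  expect_false(check_monitoring_coverage(day_only))
  # 2 h + 1.5 h daytime blocks and 3 h of night coverage
  split_day <- stream_from_runs(list(c(9.5, 11.5) * 3600, c(12, 13.5) * 3600,
                                     c(21, 24.2) * 3600))
  res <- check_monitoring_coverage(split_day)
  expect_true(res)
  expect_equal(attr(res, "day_hours"), 3.5, tolerance = 1e-3)
  expect_equal(attr(res, "night_hours"), 3.2, tolerance = 1e-3)
  no_anchor <- ok
  attr(no_anchor, "recording_start") <- NULL
  expect_error(check_monitoring_coverage(no_anchor), "recording_start")
})

test_that("AF excision removes the buffered window exactly", {
  bs <- stream_from_runs(list(c(0, 2000)))
  cut <- excise_af_intervals(bs, af_intervals(600, 900), buffer_s = 150)
  expect_false(any(cut$time_s >= 450 & cut$time_s < 1050))
  expect_true(any(abs(cut$time_s - 449) < 0.5))   # beat just before survives
  expect_true(any(abs(cut$time_s - 1050) < 0.5))  # half-open: 1050 retained
  expect_identical(excise_af_intervals(bs, af_intervals()), bs)
  expect_equal(attr(cut, "gaps")$reason, "af_excision")
})

test_that("overlapping removal windows are unioned before excision", {
  bs <- stream_from_runs(list(c(0, 1000)))
  cut <- remove_beats_in_intervals(bs, tibble::tibble(start_s = c(100, 380),
                                                      end_s = c(400, 700)))
  expect_false(any(cut$time_s >= 100 & cut$time_s < 700))
  expect_equal(nrow(attr(cut, "gaps")), 1)  # merged to [100, 700)
  expect_equal(attr(cut, "gaps")$start_s, 100)
  expect_equal(attr(cut, "gaps")$end_s, 700)
})

test_that("cleaning removes O beats and flags the resulting gaps", {
  bs <- beat_stream(c(0, 0.8, 1.6, 2.4), c("N", "N", "O", "N"))
  cl <- clean_beats(bs)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$gap_before, c(TRUE, FALSE, TRUE))
  expect_equal(attr(cl, "n_removed_other"), 1L)
  all_n <- beat_stream(c(0, 0.8, 1.6), rep("N", 3))
  expect_equal(clean_beats(all_n)$time_s, all_n$time_s)
  # 5% O beats: output count is exact
  set.seed(1)
  lab <- rep("N", 1000); lab[sample(1000, 50)] <- "O"
  big <- beat_stream(seq(0, 999) * 0.8, lab)
  expect_equal(nrow(clean_beats(big)), 950)
})

test_that("short gaps are interpolated by local median RR, long gaps kept", {
  # 800 ms context with a 1.6 s hole: one beat inserted at the midpoint
  t <- c(seq(0, 8, by = 0.8), seq(9.6, 16, by = 0.8))
  bs <- beat_stream(t, rep("N", length(t)),
                    gap_before = c(TRUE, rep(FALSE, 10), TRUE, rep(FALSE, 8)))
  ip <- interpolate_short_gaps(bs)
  expect_equal(nrow(ip), length(t) + 1)
  expect_true(any(abs(ip$time_s - 8.8) < 1e-9))
  expect_false(any(ip$gap_before[-1]))
  # a 5-s hole stays a boundary
  t2 <- c(seq(0, 8, by = 0.8), seq(13, 20, by = 0.8))
  bs2 <- beat_stream(t2, rep("N", length(t2)),
                     gap_before = c(TRUE, rep(FALSE, 10), TRUE, rep(FALSE, 8)))
  ip2 <- interpolate_short_gaps(bs2)
  expect_equal(nrow(ip2), length(t2))
  expect_true(ip2$gap_before[12])
  # gapless stream is untouched
  bs3 <- beat_stream(seq(0, 8, by = 0.8), rep("N", 11))
  expect_equal(interpolate_short_gaps(bs3)$time_s, bs3$time_s)
})

test_that("5-min segmentation tiles, discards tails, and merges across gaps", {
  # 14-min contiguous run at 1-s RR: two segments, 4-min tail discarded
  bs <- stream_from_runs(list(c(0, 840)))
  segs <- segment_rr_5min(bs)
  expect_equal(nrow(segs), 2)
  expect_true(all(segs$span_s >= 300))
  expect_equal(segs$hour_index, c(0L, 0L))
  # 4-min run, long gap, 4-min run: one merged segment (gap time excluded)
  bs2 <- stream_from_runs(list(c(0, 240), c(250, 490)))
  bs2$gap_before[bs2$time_s == 250] <- TRUE
  segs2 <- segment_rr_5min(bs2)
  expect_equal(nrow(segs2), 1)
  expect_gte(segs2$span_s, 300)
  # 299 s of data: nothing
  bs3 <- stream_from_runs(list(c(0, 299)))
  expect_equal(nrow(segment_rr_5min(bs3)), 0)
})

test_that("segment bookkeeping conserves monitored time", {
  bs <- simulate_rr_series(rr_profile(), 1.5, seed = 31)
  bs <- insert_monitoring_gaps(bs, list(rate_per_hour = 2, mean_s = 240, min_s = 60), 5)
  segs <- preprocess_stream(bs)
  expect_true(all(segs$span_s >= 300))
  mon <- intervals_total(monitored_intervals(bs))
  expect_lte(sum(segs$span_s), mon + 1)
  # spans are disjoint in cumulative-RR time by construction; check counts
  expect_true(all(segs$n_normal + segs$n_sves + segs$n_ves ==
                    vapply(segs$rr, length, integer(1))))
})

test_that("raw-ECG windows enforce beat-count and label validity rules", {
  # 60 s record at 500 Hz; beats at 0.8 s except: window 1 has 2 beats,
  # window 3 contains an O-labelled beat
  t <- seq(0.4, 59.6, by = 0.8)
  keep <- !(t > 1.2 & t < 5.12) | t < 1.3
  t <- t[keep]
  lab <- rep("N", length(t))
  lab[t > 10.24 & t < 15.36][1] <- "O"
  bs <- beat_stream(t, lab, duration_s = 60)
  rec <- structure(list(patient_id = "p1", fs = 500,
                        samples = rnorm(60 * 500, 0, 0.05), start_s = 0),
                   class = "ecg_record")
  segs <- segment_raw_ecg(rec, bs, n_select = 100, seed = 1)
  expect_false(1 %in% segs$window_id)   # fewer than three beats
  expect_false(3 %in% segs$window_id)   # O beat inside
  expect_equal(attr(segs, "n_windows"), floor(60 / 5.12))
  # reproducible subsampling of valid windows
  rec2 <- structure(list(patient_id = "p2", fs = 500,
                         samples = rnorm(512 * 500, 0, 0.05), start_s = 0),
                    class = "ecg_record")
  t2 <- seq(0.4, 511.6, by = 0.8)
  bs2 <- beat_stream(t2, rep("N", length(t2)), duration_s = 512)
  s80a <- segment_raw_ecg(rec2, bs2, n_select = 80, seed = 9)
  s80b <- segment_raw_ecg(rec2, bs2, n_select = 80, seed = 9)
  expect_equal(nrow(s80a), 80)
  expect_equal(attr(s80a, "n_valid"), 100)
  expect_identical(s80a$window_id, s80b$window_id)
  expect_equal(length(s80a$samples[[1]]), 2560)
})

test_that("the band-pass filter is near-idempotent on band-limited input", {
  set.seed(2)
  bf <- signal::butter(4, c(0.5, 50) / 250, type = "pass")
  x <- signal::filtfilt(bf, rnorm(2560))
  y <- signal::filtfilt(bf, x)
  # energy of the second pass stays close to the first: passband is preserved
  expect_gt(sum(y^2) / sum(x^2), 0.9)
  expect_lt(mean((y - x)^2) / mean(x^2), 0.05)
})
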