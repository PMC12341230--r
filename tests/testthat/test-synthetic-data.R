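test_that("zero-modulation profile degenerates to a metronome", {
  bs <- simulate_rr_series(rr_profile(mean_rr = 800, lf_amp = 0, hf_amp = 0,
                                      noise_amp = 0), 1, seed = 1)
  expect_true(abs(nrow(bs) - 4500) <= 1)
  expect_equal(unique(round(diff(bs$time_s) * 1000, 6)), 800)
  expect_true(all(bs$label == "N"))
  expect_true(all(diff(bs$time_s) > 0))
})

test_that("RR generation is deterministic and rejects invalid profiles", {
  a <- simulate_rr_series(rr_profile(), 0.5, seed = 42)
  b <- simulate_rr_series(rr_profile(), 0.5, seed = 42)
  expect_identical(a$time_s, b$time_s)
  expect_error(rr_profile(mean_rr = -5), "Invalid profile")
  expect_error(simulate_rr_series(rr_profile(), 0, seed = 1), "duration")
})

test_that("HF-only modulation concentrates tachogram power in the HF band", {
  bs <- simulate_rr_series(rr_profile(mean_rr = 800, lf_amp = 0, hf_amp = 40,
                                      noise_amp = 0), 0.5, seed = 3)
  rr <- diff(bs$time_s) * 1000
  # independent periodogram oracle on the uniformly resampled tachogram
  t_s <- cumsum(rr) / 1000
  x <- spline(t_s, rr, xout = seq(t_s[1], max(t_s), by = 0.25))$y
  sp <- stats::spec.pgram(stats::ts(x, frequency = 4), plot = FALSE, taper = 0)
  hf <- sum(sp$spec[sp$freq >= 0.15 & sp$freq < 0.4])
  tot <- sum(sp$spec[sp$freq >= 0.003 & sp$freq < 0.4])
  expect_gt(hf / tot, 0.8)
})

test_that("ectopy injection matches Poisson rates and keeps the stream sane", {
  bs <- simulate_rr_series(rr_profile(), 1, seed = 5)
  expect_identical(inject_ectopy(bs, 0, 0, seed = 1), bs)
  counts <- vapply(1:200, function(s) {
    sum(inject_ectopy(bs, 36, 0, seed = s)$label == "S")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 36), 3 * sqrt(36 / 200) + 0.5)
  one <- inject_ectopy(bs, 36, 10, seed = 7)
  expect_true(all(one$label %in% c("N", "S", "V")))
  expect_true(all(diff(one$time_s) > 0))
  expect_equal(nrow(one), nrow(bs))
})

test_that("AF episodes are >= 30 s, serially independent, and optional", {
  bs <- simulate_rr_series(rr_profile(), 1, seed = 6)
  none <- inject_af_episodes(bs, 0, seed = 1)
  expect_identical(none$stream, bs)
  expect_equal(nrow(none$af), 0)
  res <- inject_af_episodes(bs, 4, duration_mean_s = 120, seed = 8)
  expect_gt(nrow(res$af), 0)
  expect_true(all(res$af$end_s - res$af$start_s >= 30))
  rr_in <- diff(res$stream$time_s[in_intervals(res$stream$time_s, res$af)])
  r1 <- cor(rr_in[-1], rr_in[-length(rr_in)])
  expect_lt(abs(r1), 0.15)
  expect_true(all(diff(res$stream$time_s) > 0))
})

test_that("monitoring gaps remove exactly the flagged spans", {
  bs <- simulate_rr_series(rr_profile(), 1, seed = 9)
  expect_identical(insert_monitoring_gaps(bs, list(rate_per_hour = 0, mean_s = 1, min_s = 1), 1), bs)
  gap <- af_intervals(1000, 1600)  # one 10-min gap
  cut <- remove_beats_in_intervals(bs, gap, reason = "dropout")
  expect_equal(sum(in_intervals(cut$time_s, gap)), 0)
  lost <- intervals_total(monitored_intervals(bs)) -
    intervals_total(monitored_intervals(cut))
  expect_lt(abs(lost - 600), 3)   # up to one RR of slack at each edge
  expect_equal(attr(cut, "gaps")$reason, "dropout")
  # Monte-Carlo: mean total gap time matches rate x mean length
  tot <- vapply(1:100, function(s) {
    g <- attr(insert_monitoring_gaps(bs, list(rate_per_hour = 2, mean_s = 120, min_s = 30), s), "gaps")
    intervals_total(g)
  }, numeric(1))
  expect_lt(abs(mean(tot) - 2 * 120), 60)
})

test_that("clinical covariates follow configured group contrasts and ranges", {
  eff0 <- cohort_effect_sizes(age_shift_years = 0)
  a0 <- vapply(1:300, function(s) sample_clinical_features("ndaf", eff0, s)$age, numeric(1))
  b0 <- vapply(1:300, function(s) sample_clinical_features("no_af", eff0, s + 1000)$age, numeric(1))
  expect_lt(abs(mean(a0) - mean(b0)), 2.5)
  eff <- cohort_effect_sizes()
  a1 <- vapply(1:500, function(s) sample_clinical_features("ndaf", eff, s)$age, numeric(1))
  b1 <- vapply(1:500, function(s) sample_clinical_features("no_af", eff, s + 1000)$age, numeric(1))
  expect_lt(abs((mean(a1) - mean(b1)) - eff$age_shift_years), 2)
  one <- sample_clinical_features("no_af", eff, 77)
  expect_true(one$gfr > 0)
  expect_true(one$nihss >= 0 && one$nihss <= 42 && one$nihss == round(one$nihss))
  expect_true(one$mrs >= 0 && one$mrs <= 6)
})

test_that("cohort generation is deterministic, label-consistent, and on-prevalence", {
  cfg <- cohort_config(n_patients = 3, monitoring_hours = 0.2, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  # no_af patients never carry alarm intervals
  coh <- shared_cohort()
  for (i in which(coh$label == "no_af")) expect_equal(nrow(coh$af[[i]]), 0)
  # AF-prone latent short-term variability exceeds controls by the set ratio
  hf_af <- vapply(coh$truth[coh$label != "no_af"], function(tr) tr$hf_amp, numeric(1))
  hf_no <- vapply(coh$truth[coh$label == "no_af"], function(tr) tr$hf_amp, numeric(1))
  expect_gt(median(hf_af) / median(hf_no), 1.2)  # ratio 1.5 up to phenotype jitter
  # prevalence at n = 1000 within the binomial 99% interval
  cfg2 <- cohort_config(n_patients = 1000, af_prevalence = 0.06,
                        monitoring_hours = 1 / 60, seed = 7,
                        dropout = list(rate_per_hour = 0, mean_s = 1, min_s = 1))
  labs <- simulate_cohort(cfg2)$label
  ci <- qbinom(c(0.005, 0.995), 1000, 0.06)
  expect_true(sum(labs == "ndaf") >= ci[1] && sum(labs == "ndaf") <= ci[2])
})

test_that("synthetic ECG places recoverable R peaks and drops P waves in AF", {
  bs <- simulate_rr_series(rr_profile(mean_rr = 850, noise_amp = 10), 0.1, seed = 4)
  ecg <- synthesize_ecg(bs, seed = 1)
  expect_equal(length(ecg$samples), ceiling(attr(bs, "duration_s") * 500))
  peaks <- oracle_rpeaks(ecg$samples, 500)
  hits <- vapply(bs$time_s, function(t) any(abs(peaks - t) <= 0.02), logical(1))
  expect_gte(mean(hits), 0.99)
  # P-wave suppression inside a declared AF interval (noise-free synthesis)
  af <- af_intervals(10, 45)
  clean <- synthesize_ecg(bs, af, seed = 1, noise_sd = 0)
  p_amp <- function(t) max(clean$samples[round((t - 0.21) * 500):round((t - 0.15) * 500)])
  inside <- bs$time_s[bs$time_s > 12 & bs$time_s < 43]
  outside <- bs$time_s[bs$time_s > 47 & bs$time_s < 300]
  expect_lt(max(vapply(inside, p_amp, numeric(1))), 0.09)
  expect_gt(min(vapply(outside, p_amp, numeric(1))), 0.09)
})

test_that("cohort round-trips through the plain-text writers", {
  coh <- simulate_cohort(cohort_config(n_patients = 2, monitoring_hours = 0.1,
                                       af_prevalence = 0.5, seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  bs <- read_beat_csv(file.path(dir, "p0001_beats.csv"), patient_id = "p0001")
  expect_equal(bs$time_s, coh$beats[[1]]$time_s)
  expect_equal(bs$label, coh$beats[[1]]$label)
  af <- read_alarm_csv(file.path(dir, "p0001_alarms.csv"))
  expect_equal(nrow(af), nrow(coh$af[[1]]))
  clin <- utils::read.csv(file.path(dir, "clinical.csv"))
  expect_equal(nrow(clin), 2)
})
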