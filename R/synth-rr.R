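#' Latent sinus-rhythm profile for RR-series generation
#'
#' Parameters of the integral-pulse-frequency-modulation (IPFM) generator:
#' a base RR interval modulated by low-frequency (LF, default 0.1 Hz) and
#' high-frequency (HF, default 0.25 Hz) sinusoids plus `1/f^beta` broadband
#' noise. LF/HF amplitudes and the noise amplitude are in ms; `noise_beta`
#' sets the spectral slope of the broadband component (0 = white, 1 = pink),
#' which controls the long-range correlation (DFA scaling) of the series.
#'
#' @param mean_rr base RR interval, ms (> 0).
#' @param lf_amp,hf_amp amplitudes of the LF/HF sinusoidal modulation, ms.
#' @param lf_freq,hf_freq modulation frequencies, Hz (defaults 0.1, 0.25 —
#'   centres of the conventional LF 0.04–0.15 and HF 0.15–0.4 Hz bands).
#' @param noise_amp standard deviation of the broadband modulation, ms.
#' @param noise_beta spectral exponent of the broadband modulation.
#' @return a list of class `rr_profile`.
#' @export
rr_profile <- function(mean_rr = 850, lf_amp = 25, hf_amp = 20,
                       lf_freq = 0.1, hf_freq = 0.25,
                       noise_amp = 20, noise_beta = 1) {
  if (!is.finite(mean_rr) || mean_rr <= 0) {
    abort("Invalid profile: `mean_rr` must be a positive number of ms.")
  }
  structure(
    list(mean_rr = mean_rr, lf_amp = lf_amp, hf_amp = hf_amp,
         lf_freq = lf_freq, hf_freq = hf_freq,
         noise_amp = noise_amp, noise_beta = noise_beta),
    class = "rr_profile"
  )
}

# 1/f^beta Gaussian noise of length n on a grid sampled at fs Hz,
# scaled to standard deviation `amp`, by spectral synthesis.
spectral_noise <- function(n, fs, beta, amp) {
  if (amp <= 0 || n < 4) return(numeric(n))
  nfft <- 2^ceiling(log2(n))
  f <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  mag <- c(0, f[-1]^(-beta / 2))
  phase <- runif(nfft / 2 + 1, 0, 2 * pi)
  half <- mag * exp(1i * phase)
  spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s * amp
}

#' Simulate a sinus-rhythm beat stream
#'
#' Generates beat times by an integral-pulse-frequency-modulation model: the
#' instantaneous RR interval is the profile's base interval plus LF and HF
#' sinusoidal modulation plus `1/f^beta` noise, evaluated on a 4 Hz grid; a
#' beat fires whenever the integrated instantaneous rate crosses an integer.
#' With all modulation amplitudes at zero the generator degenerates to a
#' metronome at `mean_rr`. All beats are labelled `"N"`.
#'
#' @param profile an [rr_profile()].
#' @param duration_hours monitored duration, hours (> 0).
#' @param seed integer seed; the same profile + seed give identical beat times.
#' @param recording_start wall-clock start of the recording (`POSIXct`).
#' @param patient_id patient identifier.
#' @return a [beat_stream()].
#' @examples
#' bs <- simulate_rr_series(rr_profile(mean_rr = 800, lf_amp = 0, hf_amp = 0,
#'                                     noise_amp = 0), 1, seed = 1)
#' nrow(bs)  # 4500 beats in one hour at 800 ms
#' @export
simulate_rr_series <- function(profile, duration_hours, seed,
                               recording_start = as.POSIXct("2022-01-01 08:00:00", tz = "UTC"),
                               patient_id = "p1") {
  if (!inherits(profile, "rr_profile")) profile <- do.call(rr_profile, as.list(profile))
  if (!is.finite(duration_hours) || duration_hours <= 0) {
    abort("`duration_hours` must be > 0.")
  }
  duration_s <- duration_hours * 3600
  fs_grid <- 4
  t_grid <- seq(0, duration_s, by = 1 / fs_grid)
  with_local_seed(seed, {
    phi_lf <- runif(1, 0, 2 * pi)
    phi_hf <- runif(1, 0, 2 * pi)
    rr_ms <- profile$mean_rr +
      profile$lf_amp * sin(2 * pi * profile$lf_freq * t_grid + phi_lf) +
      profile$hf_amp * sin(2 * pi * profile$hf_freq * t_grid + phi_hf) +
      spectral_noise(length(t_grid), fs_grid, profile$noise_beta, profile$noise_amp)
    rr_ms <- pmin(pmax(rr_ms, 300), 2500)
    rate <- 1000 / rr_ms                       # beats per second
    phase <- cumsum(c(0, (rate[-1] + rate[-length(rate)]) / 2)) / fs_grid
    n_beats <- floor(max(phase))
    beat_t <- if (n_beats >= 1) {
      c(0, approx(phase, t_grid, xout = seq_len(n_beats), ties = "ordered")$y)
    } else 0
    beat_t <- beat_t[beat_t < duration_s]
    beat_stream(beat_t, rep("N", length(beat_t)),
                patient_id = patient_id, recording_start = recording_start,
                duration_s = duration_s)
  })
}

#' Inject premature ectopic beats into a sinus beat stream
#'
#' Randomly selected normal beats are converted to supraventricular (`"S"`) or
#' ventricular (`"V"`) extrasystoles: the beat is moved earlier into the
#' preceding RR interval (prematurity 65% of the coupling interval), leaving a
#' compensatory pause to the next beat. Counts are Poisson with the requested
#' hourly rates; total beat count is unchanged.
#'
#' @param stream a [beat_stream()].
#' @param sves_rate,ves_rate expected extrasystoles per hour (>= 0).
#' @param seed integer seed.
#' @param prematurity fraction of the preceding RR at which the ectopic beat
#'   fires (0–1, default 0.65).
#' @return a [beat_stream()] with relabelled, time-shifted ectopic beats.
#' @export
inject_ectopy <- function(stream, sves_rate, ves_rate, seed, prematurity = 0.65) {
  stopifnot(sves_rate >= 0, ves_rate >= 0)
  if ((sves_rate == 0 && ves_rate == 0) || nrow(stream) < 3) return(stream)
  hours <- attr(stream, "duration_s") / 3600
  with_local_seed(derive_seed(seed, "ectopy"), {
    n_s <- rpois(1, sves_rate * hours)
    n_v <- rpois(1, ves_rate * hours)
    # beats eligible for conversion: interior normal beats with a defined RR
    eligible <- which(stream$label == "N" & !stream$gap_before)
    eligible <- setdiff(eligible, c(1L, nrow(stream)))
    n_s <- min(n_s, length(eligible))
    pick_s <- if (n_s) sort(sample(eligible, n_s)) else integer(0)
    eligible_v <- setdiff(eligible, pick_s)
    n_v <- min(n_v, length(eligible_v))
    pick_v <- if (n_v) sort(sample(eligible_v, n_v)) else integer(0)
    t <- stream$time_s
    lab <- stream$label
    for (idx in list(S = pick_s, V = pick_v)) {
      if (length(idx)) {
        t[idx] <- t[idx - 1L] + prematurity * (t[idx] - t[idx - 1L])
      }
    }
    lab[pick_s] <- "S"
    lab[pick_v] <- "V"
    bs_rebuild(tibble(time_s = t, label = lab, gap_before = stream$gap_before), stream)
  })
}

# Replace the beats inside `iv` (one interval) with serially independent beats:
# RR drawn i.i.d. lognormal with median `med_rr_s` seconds and spread `sdlog`.
splice_irregular_beats <- function(t, lab, iv, med_rr_s, sdlog, label) {
  inside <- t >= iv[1] & t < iv[2]
  t_keep <- t[!inside]
  lab_keep <- lab[!inside]
  new_t <- numeric(0)
  cur <- iv[1] + rlnorm(1, log(med_rr_s), sdlog)
  while (cur < iv[2]) {
    new_t <- c(new_t, cur)
    cur <- cur + rlnorm(1, log(med_rr_s), sdlog)
  }
  ord <- order(c(t_keep, new_t))
  list(time_s = c(t_keep, new_t)[ord],
       label = c(lab_keep, rep(label, length(new_t)))[ord])
}

#' Inject atrial-fibrillation episodes and return their alarm intervals
#'
#' Episode onsets are Poisson with rate `episode_rate` per hour; durations are
#' `min_duration_s` plus an exponential tail (AF events shorter than 30 s do
#' not qualify as AF). Overlapping episodes are merged before replacement.
#' Within each episode the original beats are replaced by beats whose RR
#' intervals are drawn i.i.d. from a broad lognormal distribution — serial
#' independence is the defining, testable property of the simulated AF
#' rhythm. The returned interval set covers exactly the replaced spans.
#'
#' @param stream a [beat_stream()].
#' @param episode_rate expected AF episodes per hour.
#' @param duration_mean_s mean of the exponential duration tail, seconds.
#' @param seed integer seed.
#' @param min_duration_s minimum episode duration (default 30 s).
#' @param rr_scale median AF RR as a fraction of the stream's median RR.
#' @param rr_sdlog lognormal spread of AF RR intervals.
#' @return list with elements `stream` (a [beat_stream()]) and
#'   `af` (an [af_intervals()] tibble).
#' @export
inject_af_episodes <- function(stream, episode_rate, duration_mean_s = 90, seed,
                               min_duration_s = 30, rr_scale = 0.82, rr_sdlog = 0.24) {
  stopifnot(min_duration_s >= 30)
  empty <- list(stream = stream, af = af_intervals())
  if (episode_rate == 0 || nrow(stream) < 3) return(empty)
  dur <- attr(stream, "duration_s")
  with_local_seed(derive_seed(seed, "af_episodes"), {
    n <- rpois(1, episode_rate * dur / 3600)
    if (n == 0) return(empty)
    starts <- runif(n, 0, max(dur - min_duration_s, 1))
    lens <- min_duration_s + rexp(n, 1 / duration_mean_s)
    iv <- intervals_clip(af_intervals(starts, starts + lens), 0, dur)
    iv <- filter(iv, .data$end_s - .data$start_s >= min_duration_s)
    if (nrow(iv) == 0) return(empty)
    med_rr_s <- median(diff(stream$time_s)) * rr_scale
    t <- stream$time_s; lab <- stream$label
    for (i in seq_len(nrow(iv))) {
      sp <- splice_irregular_beats(t, lab, c(iv$start_s[i], iv$end_s[i]),
                                   med_rr_s, rr_sdlog, "N")
      t <- sp$time_s; lab <- sp$label
    }
    gb <- c(TRUE, rep(FALSE, length(t) - 1L))
    list(
      stream = bs_rebuild(tibble(time_s = t, label = lab, gap_before = gb), stream),
      af = iv
    )
  })
}

#' Inject short atrial runs (below the 30-s AF definition)
#'
#' Short runs of irregular supraventricular beats that do not qualify as AF
#' (and therefore raise no alarm and survive AF excision). Run spans are
#' recorded in the stream's `runs` metadata so the ECG synthesizer can drop
#' P waves there; run beats are labelled `"S"`.
#'
#' @param stream a [beat_stream()].
#' @param run_rate expected runs per hour.
#' @param seed integer seed.
#' @param duration_range run duration bounds, seconds (must stay below 30 s).
#' @return a [beat_stream()] with spliced runs and updated `runs` metadata.
#' @export
inject_short_runs <- function(stream, run_rate, seed, duration_range = c(5, 20)) {
  stopifnot(duration_range[2] < 30)
  if (run_rate == 0 || nrow(stream) < 3) return(stream)
  dur <- attr(stream, "duration_s")
  with_local_seed(derive_seed(seed, "short_runs"), {
    n <- rpois(1, run_rate * dur / 3600)
    if (n == 0) return(stream)
    starts <- runif(n, 0, max(dur - duration_range[2], 1))
    lens <- runif(n, duration_range[1], duration_range[2])
    iv <- intervals_clip(af_intervals(starts, starts + lens), 0, dur)
    med_rr_s <- median(diff(stream$time_s)) * 0.75
    t <- stream$time_s; lab <- stream$label
    for (i in seq_len(nrow(iv))) {
      sp <- splice_irregular_beats(t, lab, c(iv$start_s[i], iv$end_s[i]),
                                   med_rr_s, 0.18, "S")
      t <- sp$time_s; lab <- sp$label
    }
    gb <- c(TRUE, rep(FALSE, length(t) - 1L))
    bs_rebuild(tibble(time_s = t, label = lab, gap_before = gb), stream,
               runs = intervals_union(attr(stream, "runs"), iv))
  })
}

#' Remove beats inside an interval set and log the removal as gaps
#' @param stream a [beat_stream()]
#' @param intervals normalized interval tibble
#' @param reason character tag recorded in the gap log
#' @return a [beat_stream()]
#' @keywords internal
#' @export
remove_beats_in_intervals <- function(stream, intervals, reason = "removed") {
  if (nrow(intervals) == 0 || nrow(stream) == 0) return(stream)
  intervals <- intervals_clip(intervals_normalize(intervals), 0, attr(stream, "duration_s"))
  keep <- !in_intervals(stream$time_s, intervals)
  idx <- which(keep)
  beats <- stream[idx, , drop = FALSE]
  gb <- beats$gap_before
  if (length(idx)) {
    broke <- c(idx[1] > 1L, diff(idx) > 1L)
    gb <- gb | broke
  }
  gaps <- bind_rows(attr(stream, "gaps"),
                    mutate(intervals, reason = reason))
  bs_rebuild(tibble(time_s = beats$time_s, label = beats$label, gap_before = gb),
             stream, gaps = gaps)
}

#' Insert monitoring dropouts into a beat stream
#'
#' Emulates interruptions of bedside monitoring (electrode changes, transport,
#' off-unit examinations): gap onsets are Poisson with `rate_per_hour`, gap
#' lengths are `min_s` plus an exponential tail with mean `mean_s - min_s`.
#' Beats inside gaps are removed and gap positions are recorded in the stream
#' metadata, so effective monitored time drops below time on monitor.
#'
#' @param stream a [beat_stream()].
#' @param dropout list with `rate_per_hour`, `mean_s`, `min_s`.
#' @param seed integer seed.
#' @return a [beat_stream()] with gaps removed and logged.
#' @export
insert_monitoring_gaps <- function(stream,
                                   dropout = list(rate_per_hour = 0.15, mean_s = 600, min_s = 60),
                                   seed = 1) {
  if (dropout$rate_per_hour == 0 || nrow(stream) == 0) return(stream)
  dur <- attr(stream, "duration_s")
  with_local_seed(derive_seed(seed, "gaps"), {
    n <- rpois(1, dropout$rate_per_hour * dur / 3600)
    if (n == 0) return(stream)
    starts <- runif(n, 0, dur)
    lens <- dropout$min_s + rexp(n, 1 / max(dropout$mean_s - dropout$min_s, 1))
    iv <- intervals_clip(af_intervals(starts, starts + lens), 0, dur)
    remove_beats_in_intervals(stream, iv, reason = "dropout")
  })
}
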