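#' The 19-feature HRV registry
#'
#' Names of the heart-rate-variability features computed per 5-minute RR
#' segment: six time-domain statistics (`mean_rr`, `median_rr`, `sdnn`,
#' `cvnn`, `rmssd`, `pnn50`), four spectral powers (`tp`, `lf`, `hf`,
#' `lf_hf`), five nonlinear measures (`dfa_alpha1`, `dfa_alpha2`, `sampen`,
#' `mse`, and the Poincaré ratio `sd1_sd2` with its components `sd1`, `sd2`),
#' and two ectopy ratios (`s2n`, `v2n`). Exactly 19 features are active by
#' default.
#'
#' @return character vector of 19 feature names.
#' @export
hrv_feature_registry <- function() {
  c("mean_rr", "median_rr", "sdnn", "cvnn", "rmssd", "pnn50",
    "tp", "lf", "hf", "lf_hf",
    "dfa_alpha1", "dfa_alpha2", "sampen", "mse",
    "sd1", "sd2", "sd1_sd2",
    "s2n", "v2n")
}

#' Time-domain HRV features of one RR segment
#'
#' `mean_rr` and `median_rr` (ms), `sdnn` (sample SD, n-1 denominator, ms),
#' `cvnn = sdnn / mean_rr`, `rmssd` (root mean square of successive
#' differences, ms) and `pnn50` (percentage of successive differences larger
#' than 50 ms).
#'
#' @param rr numeric RR intervals, ms (length >= 2).
#' @return one-row tibble; all-`NA` with a `missing_reason` if too short.
#' @examples
#' compute_time_domain(c(800, 820, 790, 810))$rmssd  # ~23.8 ms
#' @export
compute_time_domain <- function(rr) {
  if (length(rr) < 2) {
    return(tibble(mean_rr = NA_real_, median_rr = NA_real_, sdnn = NA_real_,
                  cvnn = NA_real_, rmssd = NA_real_, pnn50 = NA_real_,
                  missing_reason = "fewer than 2 RR intervals"))
  }
  d <- diff(rr)
  m <- mean(rr)
  s <- sd(rr)
  tibble(
    mean_rr = m,
    median_rr = median(rr),
    sdnn = s,
    cvnn = s / m,
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * sum(abs(d) > 50) / length(d),
    missing_reason = NA_character_
  )
}

# One-sided Welch power spectral density (Hann window, mean removed per
# block). Returns a tibble(freq, psd); psd in input-units^2 per Hz.
welch_psd <- function(x, fs, nperseg = 256, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[seq_len(nf)])^2 / scale
    sp[2:(nf - 1)] <- 2 * sp[2:(nf - 1)]   # one-sided
    acc <- acc + sp
  }
  tibble(freq = seq(0, fs / 2, length.out = nf), psd = acc / length(starts))
}

band_power <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$psd[psd$freq >= lo & psd$freq < hi]) * df
}

#' Frequency-domain HRV features of one RR segment
#'
#' The tachogram (RR versus cumulative beat time) is resampled to a uniform
#' 4 Hz grid by cubic spline interpolation and its power spectral density
#' estimated by Welch's method (Hann window, 256-sample blocks, 50% overlap).
#' Band powers in ms²: total power `tp` (0.003–0.4 Hz), `lf` (0.04–0.15 Hz),
#' `hf` (0.15–0.4 Hz) and the ratio `lf_hf` (missing when `hf` is zero).
#'
#' @param rr numeric RR intervals, ms, spanning >= 300 s for stable bands.
#' @param resample_hz uniform resampling rate (default 4 Hz).
#' @return one-row tibble with `tp`, `lf`, `hf`, `lf_hf`, `missing_reason`.
#' @export
compute_frequency_domain <- function(rr, resample_hz = 4) {
  if (length(rr) < 8) {
    return(tibble(tp = NA_real_, lf = NA_real_, hf = NA_real_, lf_hf = NA_real_,
                  missing_reason = "too few beats to interpolate tachogram"))
  }
  t_s <- cumsum(rr) / 1000
  grid <- seq(t_s[1], t_s[length(t_s)], by = 1 / resample_hz)
  x <- spline(t_s, rr, xout = grid, method = "fmm")$y
  psd <- welch_psd(x, resample_hz)
  tp <- band_power(psd, 0.003, 0.4)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.4)
  tibble(tp = tp, lf = lf, hf = hf,
         lf_hf = if (hf > 0) lf / hf else NA_real_,
         missing_reason = if (hf > 0) NA_character_ else "zero HF power")
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Standard DFA on the integrated, mean-centred series: for each box size the
#' profile is split into non-overlapping boxes, linearly detrended per box,
#' and the RMS fluctuation computed; the exponent is the slope of
#' log-fluctuation versus log-scale.
#'
#' @param x numeric series.
#' @param scales integer box sizes.
#' @return scaling exponent (slope), or `NA` for degenerate input.
#' @export
dfa_exponent <- function(x, scales) {
  n <- length(x)
  scales <- scales[scales >= 4 & scales <= floor(n / 4)]
  if (length(scales) < 3) return(NA_real_)
  y <- cumsum(x - mean(x))
  fl <- map_dbl(scales, function(s) {
    nb <- floor(n / s)
    m <- matrix(y[seq_len(nb * s)], nrow = s)
    tt <- seq_len(s)
    xm <- cbind(1, tt)
    resid <- m - xm %*% qr.solve(xm, m)
    sqrt(mean(resid^2))
  })
  if (any(fl <= 0)) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, log(scales)), log(fl))
  unname(fit$coefficients[2])
}

#' Sample entropy of a series
#'
#' `SampEn(m, r)`: negative log of the conditional probability that two
#' templates matching within Chebyshev tolerance `r` over `m` points still
#' match over `m + 1` points. A constant series is defined to have entropy 0.
#'
#' @param x numeric series.
#' @param m template length (default 2).
#' @param r tolerance; defaults to `0.2 * sd(x)`.
#' @return sample entropy (natural log), `NA` when undefined (no matches).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n <= m + 1) return(NA_real_)
  if (!is.finite(r) || r == 0) return(0)    # constant series: all templates match
  d <- abs(outer(x, x, "-")) < r
  nm <- n - m
  # templates i, j in 1..n-m match over m points iff d[i+k, j+k] for k = 0..m-1
  mm <- d[seq_len(nm), seq_len(nm), drop = FALSE]
  for (k in seq_len(m - 1)) {
    mm <- mm & d[(1 + k):(nm + k), (1 + k):(nm + k)]
  }
  amat <- mm & d[(1 + m):n, (1 + m):n]
  b <- sum(mm) - nm       # exclude self matches
  a <- sum(amat) - nm
  if (b <= 0 || a <= 0) return(NA_real_)
  -log(a / b)
}

coarse_grain <- function(x, scale) {
  nb <- floor(length(x) / scale)
  if (nb < 2) return(numeric(0))
  colMeans(matrix(x[seq_len(nb * scale)], nrow = scale))
}

#' Nonlinear HRV features of one RR segment
#'
#' Short- and long-scale DFA exponents (`dfa_alpha1`, scales 4–16;
#' `dfa_alpha2`, scales 16–64), sample entropy (`m = 2`, `r = 0.2 * SD`),
#' multiscale entropy `mse` (mean sample entropy over coarse-graining scales
#' 1–5 with `r` fixed from the original series), and the Poincaré descriptors
#' `sd1 = rmssd / sqrt(2)`, `sd2 = sqrt(2 * sdnn^2 - sd1^2)` and their ratio.
#' No detrending is applied before these metrics.
#'
#' @param rr numeric RR intervals, ms; DFA/MSE require length >= 100.
#' @return one-row tibble with `dfa_alpha1`, `dfa_alpha2`, `sampen`, `mse`,
#'   `sd1`, `sd2`, `sd1_sd2`, `missing_reason`.
#' @export
compute_nonlinear <- function(rr) {
  n <- length(rr)
  if (n < 2) {
    return(tibble(dfa_alpha1 = NA_real_, dfa_alpha2 = NA_real_,
                  sampen = NA_real_, mse = NA_real_,
                  sd1 = NA_real_, sd2 = NA_real_, sd1_sd2 = NA_real_,
                  missing_reason = "fewer than 2 RR intervals"))
  }
  s <- sd(rr)
  rmssd <- sqrt(mean(diff(rr)^2))
  sd1 <- rmssd / sqrt(2)
  sd2sq <- 2 * s^2 - sd1^2
  sd2 <- if (sd2sq >= 0) sqrt(sd2sq) else NA_real_
  if (n < 100) {
    return(tibble(dfa_alpha1 = NA_real_, dfa_alpha2 = NA_real_,
                  sampen = NA_real_, mse = NA_real_,
                  sd1 = sd1, sd2 = sd2,
                  sd1_sd2 = if (isTRUE(sd2 > 0)) sd1 / sd2 else NA_real_,
                  missing_reason = "fewer than 100 RR intervals for DFA/MSE"))
  }
  r_tol <- 0.2 * s
  se <- sample_entropy(rr, 2, r_tol)
  mse_vals <- map_dbl(1:5, function(sc) {
    cg <- coarse_grain(rr, sc)
    if (length(cg) <= 3) return(NA_real_)
    sample_entropy(cg, 2, r_tol)
  })
  mse <- if (any(is.finite(mse_vals))) mean(mse_vals[is.finite(mse_vals)]) else NA_real_
  a1 <- dfa_exponent(rr, 4:16)
  a2 <- dfa_exponent(rr, unique(round(exp(seq(log(16), log(64), length.out = 8)))))
  tibble(dfa_alpha1 = a1, dfa_alpha2 = a2, sampen = se, mse = mse,
         sd1 = sd1, sd2 = sd2,
         sd1_sd2 = if (isTRUE(sd2 > 0)) sd1 / sd2 else NA_real_,
         missing_reason = if (s == 0) "constant series: DFA undefined" else NA_character_)
}

#' Ectopy ratios of one RR segment
#'
#' `s2n`: supraventricular extrasystoles per normal beat; `v2n`: ventricular
#' extrasystoles per normal beat.
#'
#' @param n_normal,n_sves,n_ves beat counts of the segment.
#' @return one-row tibble with `s2n`, `v2n`, `missing_reason`.
#' @export
compute_ectopy_ratios <- function(n_normal, n_sves, n_ves) {
  if (n_normal <= 0) {
    return(tibble(s2n = NA_real_, v2n = NA_real_,
                  missing_reason = "no normal beats in segment"))
  }
  tibble(s2n = n_sves / n_normal, v2n = n_ves / n_normal,
         missing_reason = NA_character_)
}

#' Compute the 19-feature HRV vector for every 5-minute segment
#'
#' @param segments segment tibble from [segment_rr_5min()] (any number of
#'   patients bound together).
#' @return tibble: `patient_id`, `segment_id`, `start_s`, `hour_index`,
#'   the 19 registry features, and `missing_reason` (first reason, if any).
#' @export
hrv_features <- function(segments) {
  if (nrow(segments) == 0) {
    out <- tibble(patient_id = character(), segment_id = integer(),
                  start_s = numeric(), hour_index = integer())
    for (f in hrv_feature_registry()) out[[f]] <- numeric()
    out$missing_reason <- character()
    return(out)
  }
  rows <- pmap(list(segments$rr, segments$n_normal, segments$n_sves, segments$n_ves),
               function(rr, nn, ns, nv) {
    td <- compute_time_domain(rr)
    fd <- compute_frequency_domain(rr)
    nl <- compute_nonlinear(rr)
    er <- compute_ectopy_ratios(nn, ns, nv)
    reasons <- c(td$missing_reason, fd$missing_reason, nl$missing_reason, er$missing_reason)
    bind_cols(select(td, -"missing_reason"), select(fd, -"missing_reason"),
              select(nl, -"missing_reason"), select(er, -"missing_reason")) |>
      mutate(missing_reason = if (all(is.na(reasons))) NA_character_ else
               paste(stats::na.omit(reasons), collapse = "; "))
  })
  bind_cols(select(segments, "patient_id", "segment_id", "start_s", "hour_index"),
            list_rbind(rows)) |>
    relocate(all_of(hrv_feature_registry()), .after = "hour_index")
}

#' Restrict segment features to the first hours of monitoring
#'
#' Keeps only segments starting within the first `h` hours of the recording —
#' the input-reduction step behind early risk stratification (8 h, 4 h, 2 h,
#' 1 h, 30 min, 15 min, 5 min variants).
#'
#' @param features tibble from [hrv_features()] (or segments tibble).
#' @param h hours (> 0); may be fractional.
#' @return filtered tibble.
#' @export
restrict_first_hours <- function(features, h) {
  stopifnot(h > 0)
  filter(features, .data$start_s < h * 3600)
}

#' Hourly aggregation of segment HRV vectors into one row per patient
#'
#' For every feature, the mean over valid 5-minute segments within each hour
#' is computed first; these hourly means are then averaged over the hours in
#' the analysis window, giving one value per feature per patient. Features
#' missing in all segments propagate as missing.
#'
#' @param features tibble from [hrv_features()].
#' @param window optional integer set of hour indices to include (e.g. `0`
#'   for the first-hour model); `NULL` uses all hours present.
#' @return tibble, one row per patient: features plus `hours_used`,
#'   `n_segments_used`.
#' @export
hourly_aggregate <- function(features, window = NULL) {
  feats <- intersect(hrv_feature_registry(), names(features))
  if (!is.null(window)) features <- filter(features, .data$hour_index %in% window)
  if (nrow(features) == 0) {
    warn("No segments inside the aggregation window; patients excluded.")
  }
  features |>
    group_by(.data$patient_id, .data$hour_index) |>
    summarise(across(all_of(feats), ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
              n_seg = dplyr::n(), .groups = "drop") |>
    group_by(.data$patient_id) |>
    summarise(across(all_of(feats), ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
              hours_used = dplyr::n(),
              n_segments_used = sum(.data$n_seg), .groups = "drop")
}
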