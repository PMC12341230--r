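#' Synthesize a lead-II-like single-channel ECG from a beat stream
#'
#' Places a template P-QRS-T waveform (sums of Gaussians) at every beat time.
#' Inside AF intervals and recorded short atrial runs the P wave is omitted
#' and a small fibrillatory baseline oscillation is added; ventricular
#' extrasystoles get a widened, inverted-polarity QRS and no P wave.
#' Broadband Gaussian measurement noise is added everywhere.
#'
#' @param stream a [beat_stream()].
#' @param af an [af_intervals()] tibble (may be empty).
#' @param fs sampling rate, Hz (default 500).
#' @param seed integer seed for the noise.
#' @param noise_sd measurement-noise standard deviation, mV.
#' @return an `ecg_record`: list with `patient_id`, `fs`, `samples` (mV),
#'   `start_s` (offset of the first sample, always 0 here).
#' @export
synthesize_ecg <- function(stream, af = af_intervals(), fs = 500, seed = 1,
                           noise_sd = 0.02) {
  dur <- attr(stream, "duration_s")
  n <- ceiling(dur * fs)
  no_p_zones <- intervals_union(af, attr(stream, "runs"))
  with_local_seed(derive_seed(seed, "ecg"), {
    x <- rnorm(n, 0, noise_sd)
    # fibrillatory baseline inside AF/run zones: ~6.5 Hz oscillation
    if (nrow(no_p_zones)) {
      phi <- runif(1, 0, 2 * pi)
      for (i in seq_len(nrow(no_p_zones))) {
        i0 <- max(1L, floor(no_p_zones$start_s[i] * fs) + 1L)
        i1 <- min(n, ceiling(no_p_zones$end_s[i] * fs))
        if (i1 >= i0) {
          tt <- (seq(i0, i1) - 1) / fs
          x[i0:i1] <- x[i0:i1] + 0.045 * sin(2 * pi * 6.5 * tt + phi)
        }
      }
    }
    add_gauss <- function(center_t, amp, sd_s) {
      i0 <- max(1L, floor((center_t - 4 * sd_s) * fs) + 1L)
      i1 <- min(n, ceiling((center_t + 4 * sd_s) * fs))
      if (i1 < i0) return(invisible(NULL))
      tt <- (seq(i0, i1) - 1) / fs
      x[i0:i1] <<- x[i0:i1] + amp * exp(-0.5 * ((tt - center_t) / sd_s)^2)
      invisible(NULL)
    }
    t <- stream$time_s
    lab <- stream$label
    suppress_p <- in_intervals(t, no_p_zones) | lab %in% c("S", "V")
    rr_prev <- c(0.8, diff(t))
    for (k in seq_along(t)) {
      if (lab[k] == "V") {
        add_gauss(t[k], -0.9, 0.03)           # wide, inverted ventricular complex
        add_gauss(t[k] + 0.12, 0.35, 0.06)
        next
      }
      if (!suppress_p[k]) add_gauss(t[k] - 0.18, 0.13, 0.022)
      add_gauss(t[k] - 0.028, -0.12, 0.010)   # Q
      add_gauss(t[k], 1.00, 0.012)            # R
      add_gauss(t[k] + 0.030, -0.18, 0.010)   # S
      add_gauss(t[k] + 0.30 * sqrt(min(rr_prev[k], 1.5)), 0.28, 0.050)  # T
    }
    structure(list(patient_id = attr(stream, "patient_id"), fs = fs,
                   samples = x, start_s = 0),
              class = "ecg_record")
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> patient %s: %d samples at %g Hz (%.1f min)\n",
              x$patient_id, length(x$samples), x$fs,
              length(x$samples) / x$fs / 60))
  invisible(x)
}
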