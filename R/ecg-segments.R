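#' Tile a raw ECG record into validated, band-pass-filtered 5.12-s segments
#'
#' The record is cut into non-overlapping windows of `fs * 5.12` samples
#' (2560 at 500 Hz), anchored at the record start. Each window is band-pass
#' filtered with a zero-phase (forward-backward) Butterworth filter,
#' passband 0.5–50 Hz, order 4. A window is *valid* only if it contains at
#' least three heartbeats and no beat labelled outside `{N, S, V}`; since AF
#' excision removes beats, windows inside excised spans fail the beat-count
#' rule automatically. From the valid windows, `n_select` are sampled
#' uniformly without replacement under `seed` (all of them, with a warning,
#' if fewer are available).
#'
#' @param record an `ecg_record` (see [synthesize_ecg()]).
#' @param stream the patient's [beat_stream()], sharing the record time base;
#'   pass the AF-excised stream (or supply `af` to excise here).
#' @param af optional [af_intervals()] to excise before windowing.
#' @param n_select number of valid windows to sample (default 80).
#' @param seed integer seed for the window sampling.
#' @param window_s window length, seconds (default 5.12).
#' @param band passband, Hz (default `c(0.5, 50)`).
#' @param order Butterworth order (default 4).
#' @param min_beats minimum beats per valid window (default 3).
#' @param on_fs_mismatch `"reject"` (error) or `"resample"` (linear
#'   resampling to 500 Hz) when `record$fs != 500`.
#' @return tibble of selected segments: `window_id`, `start_s`, `beat_count`,
#'   and list-columns `labels`, `samples` (filtered, length `fs * window_s`).
#'   Attributes `n_windows` and `n_valid` report the funnel counts. Zero rows
#'   (with a warning) mean the patient is ineligible for the raw-ECG model.
#' @export
segment_raw_ecg <- function(record, stream, af = NULL, n_select = 80, seed = 1,
                            window_s = 5.12, band = c(0.5, 50), order = 4,
                            min_beats = 3, on_fs_mismatch = c("reject", "resample")) {
  on_fs_mismatch <- match.arg(on_fs_mismatch)
  fs <- record$fs
  if (fs != 500) {
    if (on_fs_mismatch == "reject") {
      abort(sprintf("ECG sampled at %g Hz, expected 500 Hz.", fs))
    }
    n_new <- round(length(record$samples) / fs * 500)
    record$samples <- approx(seq_along(record$samples) / fs,
                             record$samples,
                             xout = seq_len(n_new) / 500, rule = 2)$y
    record$fs <- fs <- 500
  }
  if (!is.null(af) && nrow(af)) stream <- excise_af_intervals(stream, af)
  wlen <- round(fs * window_s)
  n_win <- floor(length(record$samples) / wlen)
  empty <- tibble(window_id = integer(), start_s = numeric(),
                  beat_count = integer(), labels = list(), samples = list())
  if (n_win == 0) {
    warn("Record shorter than one window; no raw-ECG segments.")
    return(structure(empty, n_windows = 0L, n_valid = 0L))
  }
  starts <- (seq_len(n_win) - 1) * window_s
  win_of_beat <- findInterval(stream$time_s, c(starts, n_win * window_s),
                              left.open = FALSE)
  in_range <- win_of_beat >= 1 & win_of_beat <= n_win
  counts <- tabulate(win_of_beat[in_range], nbins = n_win)
  bad_label <- tabulate(win_of_beat[in_range & stream$label == "O"], nbins = n_win)
  valid <- counts >= min_beats & bad_label == 0
  n_valid <- sum(valid)
  if (n_valid == 0) {
    warn(sprintf("Patient %s: no valid 5.12-s windows; ineligible for the raw-ECG model.",
                 record$patient_id))
    return(structure(empty, n_windows = n_win, n_valid = 0L))
  }
  chosen <- with_local_seed(derive_seed(seed, paste0("ecgseg_", record$patient_id)), {
    pool <- which(valid)
    if (length(pool) <= n_select) {
      if (length(pool) < n_select) {
        warn(sprintf("Patient %s: only %d valid windows available (requested %d).",
                     record$patient_id, length(pool), n_select))
      }
      sort(pool)
    } else {
      sort(sample(pool, n_select))
    }
  })
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  seg_rows <- map(chosen, function(w) {
    i0 <- (w - 1L) * wlen + 1L
    raw <- record$samples[i0:(i0 + wlen - 1L)]
    filt <- signal::filtfilt(bf, raw)
    beats_in <- in_range & win_of_beat == w
    tibble(window_id = w, start_s = starts[w],
           beat_count = counts[w],
           labels = list(stream$label[beats_in]),
           samples = list(filt))
  })
  structure(list_rbind(seg_rows), n_windows = n_win, n_valid = n_valid)
}
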