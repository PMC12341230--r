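#' Day/night monitoring-coverage eligibility check
#'
#' A patient is eligible for CEM analysis only if at least `min_hours` of
#' effective monitoring fall within the core daytime window (09:00–18:00)
#' *and* at least `min_hours` within the core nighttime window (21:00–06:00),
#' accumulated over the whole record. Monitored time is the union of
#' contiguous beat runs (gaps excluded), anchored to wall clock via the
#' stream's `recording_start`.
#'
#' @param stream a [beat_stream()] with a wall-clock `recording_start`.
#' @param min_hours required coverage per window, hours (default 3).
#' @param day,night core windows as `c(start_hour, end_hour)`; the night
#'   window wraps past midnight.
#' @return `TRUE` or `FALSE`; attributes `day_hours` and `night_hours` carry
#'   the accumulated coverage.
#' @export
check_monitoring_coverage <- function(stream, min_hours = 3,
                                      day = c(9, 18), night = c(21, 6)) {
  rs <- attr(stream, "recording_start")
  if (is.null(rs) || !inherits(rs, "POSIXct")) {
    abort("Beat stream has no wall-clock `recording_start`; coverage is undefined.")
  }
  mon <- monitored_intervals(stream)
  if (nrow(mon) == 0) {
    return(structure(FALSE, day_hours = 0, night_hours = 0))
  }
  lt <- as.POSIXlt(rs)
  sec0 <- lt$hour * 3600 + lt$min * 60 + lt$sec   # seconds-of-day at t = 0
  abs_iv <- tibble(start_s = mon$start_s + sec0, end_s = mon$end_s + sec0)
  ndays <- ceiling(max(abs_iv$end_s) / 86400) + 1
  window_set <- function(h0, h1) {
    d <- 0:ndays
    if (h1 > h0) {
      tibble(start_s = d * 86400 + h0 * 3600, end_s = d * 86400 + h1 * 3600)
    } else {  # wraps midnight
      tibble(start_s = d * 86400 + h0 * 3600, end_s = (d + 1) * 86400 + h1 * 3600)
    }
  }
  cov <- function(win) intervals_total(intervals_intersect(abs_iv, win)) / 3600
  day_h <- cov(window_set(day[1], day[2]))
  night_h <- cov(window_set(night[1], night[2]))
  structure(day_h >= min_hours && night_h >= min_hours,
            day_hours = day_h, night_hours = night_h)
}

#' Excise AF alarm intervals (with safety buffer) from a beat stream
#'
#' Removes every beat falling within `[start - buffer_s, end + buffer_s)` of
#' any AF alarm interval — the 2.5-minute buffer on each side ensures
#' comprehensive removal of AF-related activity before sinus-rhythm analysis.
#' Buffered windows are clipped at the record boundaries, overlapping windows
#' are merged, and the removal is logged in the stream's gap metadata.
#'
#' @param stream a [beat_stream()].
#' @param af an [af_intervals()] tibble.
#' @param buffer_s buffer on each side, seconds (default 150 = 2.5 min).
#' @return a [beat_stream()] free of AF(-adjacent) beats.
#' @export
excise_af_intervals <- function(stream, af, buffer_s = 150) {
  if (nrow(af) == 0) return(stream)
  buffered <- af_intervals(pmax(af$start_s - buffer_s, 0), af$end_s + buffer_s)
  remove_beats_in_intervals(stream, buffered, reason = "af_excision")
}

#' Remove beats not labelled normal, SVES or VES
#'
#' Beats with label `"O"` (artefact/other) are entirely removed; the RR
#' interval across each removal point becomes undefined (a gap flag on the
#' following beat) rather than being bridged. The number of removed beats is
#' recorded in the `n_removed_other` attribute.
#'
#' @param stream a [beat_stream()].
#' @return a cleaned [beat_stream()] with labels in `{N, S, V}`.
#' @export
clean_beats <- function(stream) {
  drop <- stream$label == "O"
  if (!any(drop)) {
    return(structure(stream, n_removed_other = 0L))
  }
  idx <- which(!drop)
  gb <- stream$gap_before[idx]
  broke <- c(idx[1] > 1L, diff(idx) > 1L)
  out <- bs_rebuild(tibble(time_s = stream$time_s[idx], label = stream$label[idx],
                           gap_before = gb | broke), stream)
  structure(out, n_removed_other = sum(drop))
}

# median RR (ms) in a +-window_s neighbourhood of beat i, from defined RRs
local_median_rr <- function(time_s, rr, i, window_s = 60) {
  sel <- abs(time_s - time_s[i]) <= window_s & !is.na(rr)
  if (!any(sel)) return(median(rr, na.rm = TRUE))
  median(rr[sel])
}

#' Interpolate short gaps left by beat removal
#'
#' For every gap shorter than `max_gap_s`, plausible beat times are inserted
#' by local-RR interpolation: `round(gap / local median RR) - 1` beats, evenly
#' spaced across the gap, labelled `"N"`, after which the gap flag is cleared.
#' Gaps of `max_gap_s` or longer are left untouched and keep their flag —
#' they become segment boundaries downstream.
#'
#' @param stream a cleaned [beat_stream()].
#' @param max_gap_s interpolation threshold, seconds (default 3).
#' @return a [beat_stream()] with short gaps filled.
#' @export
interpolate_short_gaps <- function(stream, max_gap_s = 3) {
  n <- nrow(stream)
  if (n < 2) return(stream)
  rr <- beat_rr(stream)
  gap_idx <- which(stream$gap_before & seq_len(n) > 1L)
  if (!length(gap_idx)) return(stream)
  new_t <- list(); new_lab <- list()
  clear <- logical(n)
  for (i in gap_idx) {
    gap_s <- stream$time_s[i] - stream$time_s[i - 1L]
    if (gap_s >= max_gap_s) next
    med <- local_median_rr(stream$time_s, rr, i)
    if (!is.finite(med) || med <= 0) next
    k <- max(round(gap_s * 1000 / med) - 1, 0)
    if (k > 0) {
      step <- gap_s / (k + 1)
      new_t[[length(new_t) + 1L]] <- stream$time_s[i - 1L] + step * seq_len(k)
      new_lab[[length(new_lab) + 1L]] <- rep("N", k)
    }
    clear[i] <- TRUE
  }
  t_all <- c(stream$time_s, unlist(new_t))
  lab_all <- c(stream$label, unlist(new_lab))
  gb_all <- c(stream$gap_before & !clear, rep(FALSE, length(unlist(new_t))))
  ord <- order(t_all)
  bs_rebuild(tibble(time_s = t_all[ord], label = lab_all[ord],
                    gap_before = gb_all[ord]), stream)
}

#' Segment a cleaned beat stream into 5-minute RR segments
#'
#' RR data between long-gap boundaries are concatenated (gap time excluded)
#' and tiled greedily into windows of at least `segment_s` seconds of
#' cumulative RR time; the residual tail shorter than `segment_s` is
#' discarded. Concatenating across long gaps before re-tiling minimises data
#' loss: a 4-min run, a long gap and another 4-min run still yield one merged
#' 5-min segment. Each segment is tagged with the hour index (since recording
#' start) of its first beat.
#'
#' @param stream a cleaned, gap-interpolated [beat_stream()].
#' @param segment_s segment length, seconds (default 300).
#' @return tibble with one row per segment: `patient_id`, `segment_id`,
#'   `start_s`, `hour_index`, `span_s`, `n_normal`, `n_sves`, `n_ves` and a
#'   list-column `rr` of RR values (ms).
#' @export
segment_rr_5min <- function(stream, segment_s = 300) {
  empty <- tibble(patient_id = character(), segment_id = integer(),
                  start_s = numeric(), hour_index = integer(), span_s = numeric(),
                  n_normal = integer(), n_sves = integer(), n_ves = integer(),
                  rr = list())
  rr <- beat_rr(stream)
  ok <- !is.na(rr)
  if (!any(ok)) return(empty)
  v <- rr[ok]                       # RR values, ms, in temporal order
  t_end <- stream$time_s[ok]        # time of the beat ending each RR
  lab <- stream$label[ok]           # label of the beat ending each RR
  target_ms <- segment_s * 1000
  cum <- cumsum(v)
  seg_id <- integer(length(v))
  sid <- 1L; acc_base <- 0
  for (i in seq_along(v)) {
    seg_id[i] <- sid
    if (cum[i] - acc_base >= target_ms) {
      acc_base <- cum[i]
      sid <- sid + 1L
    }
  }
  complete <- seq_len(sid - 1L)
  if (!length(complete)) return(empty)
  rows <- map(complete, function(s) {
    sel <- seg_id == s
    tibble(
      patient_id = attr(stream, "patient_id"),
      segment_id = s,
      start_s = t_end[sel][1] - v[sel][1] / 1000,
      span_s = sum(v[sel]) / 1000,
      n_normal = sum(lab[sel] == "N"),
      n_sves = sum(lab[sel] == "S"),
      n_ves = sum(lab[sel] == "V"),
      rr = list(v[sel])
    )
  })
  out <- list_rbind(rows)
  mutate(out, hour_index = as.integer(floor(.data$start_s / 3600)),
         .after = "start_s")
}

#' Preprocess one patient's beat stream into RR segments
#'
#' Convenience chain: AF excision with buffer, removal of non-N/S/V beats,
#' short-gap interpolation, 5-minute segmentation.
#'
#' @param stream a [beat_stream()].
#' @param af an [af_intervals()] tibble.
#' @param buffer_s AF excision buffer (s).
#' @param max_gap_s gap-interpolation threshold (s).
#' @return segment tibble as from [segment_rr_5min()].
#' @export
preprocess_stream <- function(stream, af = af_intervals(),
                              buffer_s = 150, max_gap_s = 3) {
  stream |>
    excise_af_intervals(af, buffer_s = buffer_s) |>
    clean_beats() |>
    interpolate_short_gaps(max_gap_s = max_gap_s) |>
    segment_rr_5min()
}
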