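#' Labelled heartbeat stream for one monitored patient
#'
#' A `beat_stream` is a tibble with one row per detected heartbeat and columns
#' `time_s` (seconds from recording start, strictly increasing), `label`
#' (one of `"N"` normal, `"S"` supraventricular extrasystole, `"V"` ventricular
#' extrasystole, `"O"` other/artefact) and `gap_before` (logical; `TRUE` when
#' the RR interval to the previous beat is not defined — first beat of the
#' record or first beat after removed data). Patient identity, the wall-clock
#' recording start, the nominal monitored duration and a log of data gaps ride
#' along as attributes so that pipelines stay pipe-friendly.
#'
#' @param time_s numeric, strictly increasing beat times in seconds.
#' @param label character beat labels, subset of `c("N","S","V","O")`.
#' @param patient_id patient identifier (coerced to character).
#' @param recording_start wall-clock start, a `POSIXct` (needed by the
#'   day/night coverage rule). Defaults to 2022-01-01 08:00 UTC.
#' @param duration_s nominal monitored duration in seconds; defaults to the
#'   last beat time.
#' @param gap_before optional logical vector; recomputed from scratch when
#'   `NULL` (first beat only).
#' @param gaps tibble of logged gaps (`start_s`, `end_s`, `reason`).
#' @param runs tibble of short atrial-run spans (`start_s`, `end_s`), metadata
#'   used by the ECG synthesizer and by tests.
#' @return A `beat_stream` tibble.
#' @examples
#' bs <- beat_stream(time_s = c(0, 0.8, 1.6), label = c("N", "N", "N"))
#' beat_rr(bs)
#' @export
beat_stream <- function(time_s, label,
                        patient_id = "p1",
                        recording_start = as.POSIXct("2022-01-01 08:00:00", tz = "UTC"),
                        duration_s = NULL,
                        gap_before = NULL,
                        gaps = NULL,
                        runs = NULL) {
  time_s <- as.numeric(time_s)
  label <- as.character(label)
  if (length(time_s) != length(label)) abort("`time_s` and `label` lengths differ.")
  if (length(time_s) && any(diff(time_s) <= 0)) abort("Beat times must be strictly increasing.")
  if (!all(label %in% c("N", "S", "V", "O"))) abort("Beat labels must be in {N, S, V, O}.")
  if (is.null(gap_before)) {
    gap_before <- c(TRUE, rep(FALSE, max(length(time_s) - 1L, 0L)))[seq_along(time_s)]
  }
  if (is.null(duration_s)) duration_s <- if (length(time_s)) max(time_s) else 0
  if (is.null(gaps)) gaps <- tibble(start_s = numeric(), end_s = numeric(), reason = character())
  if (is.null(runs)) runs <- tibble(start_s = numeric(), end_s = numeric())
  out <- tibble(time_s = time_s, label = label, gap_before = as.logical(gap_before))
  structure(out,
    patient_id = as.character(patient_id),
    recording_start = recording_start,
    duration_s = as.numeric(duration_s),
    gaps = gaps,
    runs = runs,
    class = c("beat_stream", class(out))
  )
}

# rebuild a beat_stream keeping (or overriding) the attributes of `template`
bs_rebuild <- function(beats, template, ...) {
  override <- list(...)
  args <- list(
    time_s = beats$time_s, label = beats$label, gap_before = beats$gap_before,
    patient_id = attr(template, "patient_id"),
    recording_start = attr(template, "recording_start"),
    duration_s = attr(template, "duration_s"),
    gaps = attr(template, "gaps"),
    runs = attr(template, "runs")
  )
  args[names(override)] <- override
  do.call(beat_stream, args)
}

#' @export
print.beat_stream <- function(x, ...) {
  cat(sprintf(
    "<beat_stream> patient %s: %d beats over %.1f h (start %s)\n",
    attr(x, "patient_id"), nrow(x), attr(x, "duration_s") / 3600,
    format(attr(x, "recording_start"), "%Y-%m-%d %H:%M %Z")
  ))
  gp <- attr(x, "gaps")
  if (nrow(gp)) cat(sprintf("  %d logged gaps, %.1f min total\n", nrow(gp), intervals_total(gp) / 60))
  NextMethod()
}

#' RR intervals of a beat stream
#'
#' Returns the RR interval (ms) ending at each beat; `NA` where no RR is
#' defined (first beat of the record or first beat after a gap).
#'
#' @param stream a [beat_stream()]
#' @return numeric vector, one value per beat, ms.
#' @export
beat_rr <- function(stream) {
  if (nrow(stream) == 0) return(numeric(0))
  rr <- c(NA_real_, diff(stream$time_s) * 1000)
  rr[stream$gap_before] <- NA_real_
  rr
}

#' Effective monitored time of a beat stream
#'
#' The monitored span is the union of contiguous beat runs — consecutive beats
#' closer than `max_gap_s` apart — mirroring the distinction between time on
#' monitor and effective monitoring time.
#'
#' @param stream a [beat_stream()]
#' @param max_gap_s inter-beat spacing above which monitoring is considered
#'   interrupted (default 5 s).
#' @return tibble of covered intervals (`start_s`, `end_s`).
#' @export
monitored_intervals <- function(stream, max_gap_s = 5) {
  t <- stream$time_s
  if (length(t) < 2) return(tibble(start_s = numeric(), end_s = numeric()))
  brk <- which(diff(t) >= max_gap_s | stream$gap_before[-1])
  starts <- t[c(1L, brk + 1L)]
  ends <- t[c(brk, length(t))]
  ok <- ends > starts
  intervals_normalize(tibble(start_s = starts[ok], end_s = ends[ok]))
}
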