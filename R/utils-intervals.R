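#' Half-open interval sets on the recording time axis
#'
#' All interval bookkeeping in afstream (AF alarms, monitoring gaps, excision
#' windows) uses half-open intervals `[start_s, end_s)` in seconds from
#' recording start. `af_intervals()` builds a normalized interval set:
#' sorted, merged where overlapping or touching, all with `end_s > start_s`.
#'
#' @param start_s,end_s numeric vectors of interval bounds (seconds).
#' @return A tibble with columns `start_s`, `end_s`, normalized.
#' @examples
#' af_intervals(c(100, 380), c(400, 700))  # merges to [100, 700)
#' @export
af_intervals <- function(start_s = numeric(), end_s = numeric()) {
  if (length(start_s) != length(end_s)) {
    abort("`start_s` and `end_s` must have the same length.")
  }
  if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
    abort("Interval bounds must be finite.")
  }
  if (any(end_s <= start_s)) {
    abort("Each interval must satisfy end_s > start_s.")
  }
  intervals_normalize(tibble(start_s = as.numeric(start_s), end_s = as.numeric(end_s)))
}

#' Normalize an interval tibble: sort, merge overlapping/touching intervals
#' @param x tibble with `start_s`, `end_s`
#' @return normalized tibble
#' @keywords internal
#' @export
intervals_normalize <- function(x) {
  if (nrow(x) == 0) return(tibble(start_s = numeric(), end_s = numeric()))
  x <- arrange(x, .data$start_s, .data$end_s)
  start <- x$start_s
  end <- x$end_s
  keep_start <- start[1]
  keep_end <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  if (nrow(x) > 1) {
    for (i in 2:nrow(x)) {
      if (start[i] <= keep_end) {
        keep_end <- max(keep_end, end[i])
      } else {
        out_s <- c(out_s, keep_start); out_e <- c(out_e, keep_end)
        keep_start <- start[i]; keep_end <- end[i]
      }
    }
  }
  tibble(start_s = c(out_s, keep_start), end_s = c(out_e, keep_end))
}

#' @keywords internal
intervals_union <- function(a, b) {
  intervals_normalize(bind_rows(a, b))
}

#' Total covered length of a normalized interval set, seconds
#' @keywords internal
intervals_total <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(x$end_s - x$start_s)
}

#' Clip an interval set to a window [lo, hi)
#' @keywords internal
intervals_clip <- function(x, lo, hi) {
  if (nrow(x) == 0) return(x)
  x <- mutate(x, start_s = pmax(.data$start_s, lo), end_s = pmin(.data$end_s, hi))
  filter(x, .data$end_s > .data$start_s)
}

#' Intersection of two normalized interval sets
#' @keywords internal
intervals_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(tibble(start_s = numeric(), end_s = numeric()))
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start_s[i], b$start_s)
    e <- pmin(a$end_s[i], b$end_s)
    hit <- e > s
    out_s <- c(out_s, s[hit]); out_e <- c(out_e, e[hit])
  }
  intervals_normalize(tibble(start_s = out_s, end_s = out_e))
}

#' Membership of time points in a half-open interval set
#' @param t numeric vector of times (s)
#' @param x normalized interval tibble
#' @return logical vector, TRUE where t falls in some [start_s, end_s)
#' @keywords internal
#' @export
in_intervals <- function(t, x) {
  if (nrow(x) == 0) return(rep(FALSE, length(t)))
  # half-open: t in [start, end). findInterval on the flattened boundary vector
  # puts in-interval points at odd indices.
  bounds <- as.vector(rbind(x$start_s, x$end_s))
  findInterval(t, bounds, left.open = FALSE) %% 2L == 1L
}

# Derive a reproducible child seed from a master seed and a string key.
# Keeps results below 2^31 - 1 so set.seed() always accepts them.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

# Evaluate `code` under a local RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
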