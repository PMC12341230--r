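# Independent oracle implementations used to cross-check the package's HRV
# and evaluation code. These are deliberately written as plain loops over the
# textbook definitions, sharing no code with the package internals.

oracle_time_domain <- function(rr) {
  n <- length(rr)
  d <- rr[2:n] - rr[1:(n - 1)]
  list(
    mean_rr = sum(rr) / n,
    median_rr = median(rr),
    sdnn = sqrt(sum((rr - sum(rr) / n)^2) / (n - 1)),
    rmssd = sqrt(sum(d^2) / (n - 1)),
    pnn50 = 100 * sum(abs(d) > 50) / (n - 1),
    cvnn = sqrt(sum((rr - sum(rr) / n)^2) / (n - 1)) / (sum(rr) / n)
  )
}

# Welch PSD from the definition: explicit block loop, Hann window, one-sided.
oracle_band_power <- function(rr, lo, hi, fs = 4, nperseg = 256) {
  t_s <- cumsum(rr) / 1000
  grid <- seq(t_s[1], t_s[length(t_s)], by = 1 / fs)
  x <- spline(t_s, rr, xout = grid, method = "fmm")$y
  n <- length(x)
  nseg <- min(nperseg, n)
  step <- floor(nseg / 2)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1)) / (nseg - 1)))
  psd <- NULL
  count <- 0
  for (s0 in seq(1, n - nseg + 1, by = step)) {
    seg <- x[s0:(s0 + nseg - 1)]
    seg <- seg - mean(seg)
    X <- fft(seg * w)
    half <- (abs(X)^2 / (fs * sum(w^2)))[1:(floor(nseg / 2) + 1)]
    half[2:(length(half) - 1)] <- 2 * half[2:(length(half) - 1)]
    psd <- if (is.null(psd)) half else psd + half
    count <- count + 1
  }
  psd <- psd / count
  freq <- seq(0, fs / 2, length.out = length(psd))
  df <- freq[2] - freq[1]
  sum(psd[freq >= lo & freq < hi]) * df
}

# DFA from the definition: explicit per-box polyfit loop.
oracle_dfa <- function(x, scales) {
  y <- cumsum(x - mean(x))
  n <- length(y)
  logf <- c(); logs <- c()
  for (s in scales) {
    nb <- floor(n / s)
    if (nb < 4) next
    acc <- 0
    for (b in 1:nb) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      tt <- 1:s
      fit <- lm(seg ~ tt)
      acc <- acc + sum(residuals(fit)^2)
    }
    logf <- c(logf, 0.5 * log(acc / (nb * s)))
    logs <- c(logs, log(s))
  }
  as.numeric(coef(lm(logf ~ logs))[2])
}

# Sample entropy from the definition: explicit template-pair loop.
oracle_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  a <- 0; b <- 0
  for (i in 1:(n - m)) {
    for (j in 1:(n - m)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        b <- b + 1
        if (abs(x[i + m] - x[j + m]) < r) a <- a + 1
      }
    }
  }
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# Brute-force ROC-AUC: all positive-negative pairs, ties count one half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Simple threshold R-peak detector used as an independent check of the ECG
# synthesizer (not of any package detector).
oracle_rpeaks <- function(samples, fs, thresh = 0.4, refractory_s = 0.25) {
  above <- which(samples > thresh)
  peaks <- c()
  last <- -Inf
  for (i in above) {
    if (i > 1 && i < length(samples) &&
        samples[i] >= samples[i - 1] && samples[i] >= samples[i + 1]) {
      t <- (i - 1) / fs
      if (t - last >= refractory_s) {
        peaks <- c(peaks, t)
        last <- t
      }
    }
  }
  peaks
}

# Build a beat stream with constant RR (seconds) covering [t0, t1)
constant_run <- function(t0, t1, rr_s = 1) {
  seq(t0, t1 - 1e-9, by = rr_s)
}
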