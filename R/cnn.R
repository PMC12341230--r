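#' Train a compact 1-D convolutional network on raw-ECG segments
#'
#' A small, fully configurable convolutional classifier for 5.12-s band-pass
#' filtered ECG segments: one 1-D convolution (ReLU) over the standardized
#' trace, global average plus global max pooling per filter, and a sigmoid
#' output unit.
#' Training minimizes binary cross-entropy with the Adam optimiser for
#' `epochs` epochs at learning rate `lr` (defaults 20 and 0.001). The
#' implementation is plain matrix algebra, single-threaded, and fully
#' deterministic given the seed.
#'
#' @param segments tibble with a `samples` list-column of equal-length
#'   numeric traces (2560 samples at 500 Hz) — e.g. from
#'   [segment_raw_ecg()] rows bound over patients.
#' @param labels per-segment outcomes (0/1 or logical).
#' @param epochs,lr,batch_size training hyperparameters.
#' @param filters,kernel,stride convolution architecture; the default 128-sample
#'   kernel (256 ms at 500 Hz) spans a full P-QRS complex, which is what lets
#'   the network notice absent P waves and irregular R-R spacing.
#' @param seed integer seed for initialisation and batch shuffling.
#' @param min_per_class refuse to train with fewer segments per class.
#' @return an object of class `af_cnn`.
#' @export
train_cnn <- function(segments, labels, epochs = 20, lr = 0.001,
                      batch_size = 64, filters = 8, kernel = 128, stride = 16,
                      seed = 1, min_per_class = 10) {
  y <- as.numeric(as.logical_label(labels))
  if (min(table(y)) < min_per_class) {
    abort(sprintf("Need at least %d segments per class to train the CNN.", min_per_class))
  }
  X <- do.call(rbind, map(segments$samples, standardize_trace))
  L <- ncol(X)
  if (any(lengths(segments$samples) != L)) abort("All segments must share one length.")
  pos <- seq(1, L - kernel + 1, by = stride)
  col_idx <- outer(pos, seq_len(kernel) - 1L, "+")     # positions x kernel
  with_local_seed(derive_seed(seed, "cnn"), {
    par <- list(W = matrix(rnorm(kernel * filters, 0, sqrt(2 / kernel)), kernel, filters),
                b = numeric(filters),
                v = rnorm(2 * filters, 0, sqrt(1 / filters)),
                c = 0)
    adam <- init_adam(par)
    step <- 0
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(nrow(X))
      ep_loss <- 0
      for (b0 in seq(1, length(ord), by = batch_size)) {
        rows <- ord[b0:min(b0 + batch_size - 1, length(ord))]
        step <- step + 1
        res <- cnn_batch_grad(X[rows, , drop = FALSE], y[rows], par, col_idx)
        adam <- adam_update(par, res$grad, adam, lr, step)
        par <- adam$par
        ep_loss <- ep_loss + res$loss * length(rows)
      }
      losses[ep] <- ep_loss / nrow(X)
    }
    structure(list(kind = "cnn", par = par, col_idx = col_idx,
                   kernel = kernel, stride = stride, filters = filters,
                   length = L, losses = losses, seed = seed),
              class = "af_cnn")
  })
}

standardize_trace <- function(x) {
  s <- sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

cnn_forward <- function(X, par, col_idx) {
  n <- nrow(X); P <- nrow(col_idx); K <- ncol(col_idx)
  # im2col: A[(i-1)*P + p, k] = X[i, col_idx[p, k]]
  arr <- array(X[, as.vector(col_idx)], dim = c(n, P, K))
  A <- matrix(aperm(arr, c(2, 1, 3)), nrow = n * P)
  Z <- sweep(A %*% par$W, 2, par$b, "+")
  H <- pmax(Z, 0)
  f_n <- ncol(H)
  # global average + max pooling per filter: G is n x 2F
  G_avg <- rowsum(H, rep(seq_len(n), each = P)) / P
  G_max <- matrix(0, n, f_n)
  argmax <- matrix(0L, n, f_n)
  for (f in seq_len(f_n)) {
    M <- matrix(H[, f], nrow = P)          # (position, segment)
    argmax[, f] <- max.col(t(M), ties.method = "first")
    G_max[, f] <- M[cbind(argmax[, f], seq_len(n))]
  }
  G <- cbind(G_avg, G_max)
  eta <- as.numeric(G %*% par$v + par$c)
  p <- 1 / (1 + exp(-eta))
  list(A = A, Z = Z, H = H, G = G, argmax = argmax, p = p, n = n, P = P)
}

cnn_batch_grad <- function(X, y, par, col_idx) {
  fw <- cnn_forward(X, par, col_idx)
  n <- fw$n; P <- fw$P
  eps <- 1e-12
  loss <- -mean(y * log(fw$p + eps) + (1 - y) * log(1 - fw$p + eps))
  dscore <- (fw$p - y) / n                       # n
  dv <- as.numeric(t(fw$G) %*% dscore)
  dc <- sum(dscore)
  f_n <- ncol(fw$Z)
  dG <- outer(dscore, par$v)                     # n x 2F
  dH <- dG[rep(seq_len(n), each = P), seq_len(f_n), drop = FALSE] / P
  # max-pool branch: gradient flows to the argmax position of each filter
  for (f in seq_len(f_n)) {
    rows <- (seq_len(n) - 1L) * P + fw$argmax[, f]
    dH[rows, f] <- dH[rows, f] + dG[, f_n + f]
  }
  dZ <- dH * (fw$Z > 0)
  dW <- t(fw$A) %*% dZ
  db <- colSums(dZ)
  list(loss = loss, grad = list(W = dW, b = db, v = dv, c = dc))
}

init_adam <- function(par) {
  list(m = map(par, ~ .x * 0), v = map(par, ~ .x * 0))
}

adam_update <- function(par, grad, state, lr, step, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^step)
    vhat <- state$v[[nm]] / (1 - beta2^step)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state$par <- par
  state
}

#' Per-segment AF probabilities from a fitted CNN
#' @param object an `af_cnn`.
#' @param segments tibble with a `samples` list-column (same trace length as
#'   at training time).
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.af_cnn <- function(object, segments, ...) {
  if (nrow(segments) == 0) return(numeric(0))
  X <- do.call(rbind, map(segments$samples, standardize_trace))
  if (ncol(X) != object$length) abort("Segment length differs from training length.")
  cnn_forward(X, object$par, object$col_idx)$p
}

#' @export
print.af_cnn <- function(x, ...) {
  cat(sprintf("<af_cnn> %d filters, kernel %d, stride %d; final loss %.4f\n",
              x$filters, x$kernel, x$stride, tail(x$losses, 1)))
  invisible(x)
}

#' Aggregate per-segment CNN probabilities to patient level
#'
#' For each patient, `k` of their segment probabilities are sampled without
#' replacement (all, if fewer are available) and averaged — the rule behind
#' performance-versus-segment-count curves (1 to 80 segments per patient).
#' Patients with no segments are dropped with a warning.
#'
#' @param segment_preds tibble with `patient_id` and `prob` per segment.
#' @param k segments per patient (>= 1).
#' @param seed integer seed for the sampling.
#' @return tibble `patient_id`, `prob`, `n_segments_used`.
#' @export
aggregate_segment_predictions <- function(segment_preds, k, seed = 1) {
  stopifnot(k >= 1)
  if (nrow(segment_preds) == 0) {
    warn("No segment predictions to aggregate.")
    return(tibble(patient_id = character(), prob = numeric(),
                  n_segments_used = integer()))
  }
  with_local_seed(derive_seed(seed, "seg_agg"), {
    segment_preds |>
      group_by(.data$patient_id) |>
      group_modify(function(df, key) {
        take <- min(k, nrow(df))
        idx <- if (nrow(df) == 1) 1L else sample(nrow(df), take)
        tibble(prob = mean(df$prob[idx]), n_segments_used = take)
      }) |>
      ungroup()
  })
}
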