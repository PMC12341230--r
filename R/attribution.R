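#' Feature attribution for a fitted AF classifier
#'
#' Two complementary views of feature importance, averaged over the supplied
#' rows (typically a test fold, then averaged across folds by the caller):
#'
#' * `method = "shap"` — game-theoretic additive attribution: per-row Shapley
#'   values estimated by the kernel-weighted linear-regression formulation,
#'   with the training medians as the single background reference. The
#'   attributions of each row sum exactly to
#'   `prediction - baseline prediction` (additivity is enforced by the
#'   regression constraint). All `2^p` coalitions are enumerated when
#'   `p <= 12`, otherwise `n_coalitions` are sampled.
#' * `method = "permutation"` — mean drop in ROC-AUC when one feature column
#'   is permuted (`labels` required).
#'
#' @param model an `af_ensemble` (any object with a `predict` method over the
#'   same schema works for `"shap"`).
#' @param features data frame of predictor rows to explain.
#' @param method `"shap"` or `"permutation"`.
#' @param labels outcomes, required for `"permutation"`.
#' @param n_coalitions sampled coalitions per row when `p > 12`.
#' @param n_rows maximum rows to explain (subsampled with `seed`).
#' @param n_rep permutation repeats.
#' @param seed integer seed.
#' @return tibble `feature`, `importance` (mean |SHAP| or mean AUC drop),
#'   `mean_attribution` (signed, SHAP only), `rank`. For `"shap"`, the
#'   per-row attribution matrix is attached as attribute `shap_values`.
#' @export
feature_attribution <- function(model, features,
                                method = c("shap", "permutation"),
                                labels = NULL, n_coalitions = 256,
                                n_rows = 100, n_rep = 5, seed = 1) {
  method <- match.arg(method)
  x <- encode_features(features)
  x <- x[, model$schema, drop = FALSE]
  x <- impute_medians(x, model$medians)
  if (method == "shap") {
    shap_attribution(model, x, n_coalitions, n_rows, seed)
  } else {
    if (is.null(labels)) abort("`labels` are required for permutation importance.")
    permutation_attribution(model, x, as.integer(as.logical_label(labels)), n_rep, seed)
  }
}

shap_attribution <- function(model, x, n_coalitions, n_rows, seed) {
  p <- ncol(x)
  bg <- as_tibble(as.list(model$medians))[, names(x), drop = FALSE]
  f_bg <- predict_candidate(model$fit, bg)
  with_local_seed(derive_seed(seed, "shap"), {
    rows <- if (nrow(x) > n_rows) sort(sample(nrow(x), n_rows)) else seq_len(nrow(x))
    Z <- coalition_matrix(p, n_coalitions)
    w <- kernel_weights(Z)
    phi <- matrix(0, length(rows), p, dimnames = list(NULL, names(x)))
    for (ri in seq_along(rows)) {
      xi <- x[rows[ri], , drop = FALSE]
      hybrids <- bg[rep(1, nrow(Z)), , drop = FALSE]
      for (j in seq_len(p)) {
        on <- Z[, j] == 1
        if (any(on)) hybrids[[j]][on] <- xi[[j]]
      }
      v <- predict_candidate(model$fit, hybrids) - f_bg
      v_full <- predict_candidate(model$fit, xi) - f_bg
      phi[ri, ] <- solve_shap_wls(Z, v, w, v_full)
    }
    out <- tibble(
      feature = names(x),
      importance = colMeans(abs(phi)),
      mean_attribution = colMeans(phi)
    ) |>
      arrange(desc(.data$importance)) |>
      mutate(rank = dplyr::row_number())
    structure(out, shap_values = phi, baseline = f_bg, rows = rows)
  })
}

# coalition indicator matrix excluding the empty and full sets
coalition_matrix <- function(p, n_coalitions) {
  if (p <= 12) {
    Z <- as.matrix(expand.grid(rep(list(0:1), p)))
    Z <- Z[rowSums(Z) %in% seq_len(p - 1), , drop = FALSE]
  } else {
    sizes <- sample(seq_len(p - 1), n_coalitions, replace = TRUE,
                    prob = 1 / (seq_len(p - 1) * (p - seq_len(p - 1))))
    Z <- t(vapply(sizes, function(s) {
      z <- numeric(p); z[sample(p, s)] <- 1; z
    }, numeric(p)))
  }
  colnames(Z) <- NULL
  Z
}

kernel_weights <- function(Z) {
  p <- ncol(Z)
  s <- rowSums(Z)
  (p - 1) / (choose(p, s) * s * (p - s))
}

# weighted least squares for phi with the constraint sum(phi) = v_full
solve_shap_wls <- function(Z, v, w, v_full) {
  p <- ncol(Z)
  Zr <- Z[, -p, drop = FALSE] - Z[, p]
  vr <- v - Z[, p] * v_full
  A <- sqrt(w) * Zr
  b <- sqrt(w) * vr
  phi_r <- tryCatch(qr.solve(A, b), error = function(e) rep(0, p - 1))
  c(phi_r, v_full - sum(phi_r))
}

permutation_attribution <- function(model, x, y, n_rep, seed) {
  base_auc <- roc_auc(y, predict_candidate(model$fit, x))
  with_local_seed(derive_seed(seed, "perm_imp"), {
    drops <- vapply(names(x), function(nm) {
      mean(vapply(seq_len(n_rep), function(r) {
        xp <- x
        xp[[nm]] <- sample(xp[[nm]])
        base_auc - roc_auc(y, predict_candidate(model$fit, xp))
      }, numeric(1)))
    }, numeric(1))
    tibble(feature = names(x), importance = drops,
           mean_attribution = NA_real_) |>
      arrange(desc(.data$importance)) |>
      mutate(rank = dplyr::row_number())
  })
}
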