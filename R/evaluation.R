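#' ROC-AUC by the rank (Mann-Whitney) formulation
#'
#' Equals the probability that a random positive scores above a random
#' negative, with ties counted 1/2 — identical to brute-force pairwise
#' concordance.
#'
#' @param labels 0/1 outcomes (both classes present).
#' @param scores numeric scores, higher = more AF-like.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as.integer(as.logical_label(labels))
  if (length(unique(y)) < 2) abort("ROC-AUC needs both classes present.")
  if (length(y) != length(scores)) abort("`labels` and `scores` lengths differ.")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for the ROC-AUC
#'
#' Patients are resampled with replacement *within* each class (stratified),
#' so every resample keeps both classes; the interval is the percentile
#' interval of the resampled AUCs. Defaults follow the evaluation protocol:
#' 200 resamples per derivation fold, 1000 for validation runs.
#'
#' @param labels,scores as in [roc_auc()].
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lo, hi)`; attribute `boot_aucs` carries the
#'   resampled values.
#' @export
bootstrap_auc_ci <- function(labels, scores, n_boot = 1000, seed = 1, level = 0.95) {
  y <- as.integer(as.logical_label(labels))
  i1 <- which(y == 1)
  i0 <- which(y == 0)
  if (!length(i1) || !length(i0)) abort("Both classes are required.")
  with_local_seed(derive_seed(seed, "boot_auc"), {
    aucs <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      roc_auc(y[idx], scores[idx])
    }, numeric(1))
    a <- (1 - level) / 2
    structure(setNames(as.numeric(quantile(aucs, c(a, 1 - a), names = FALSE)),
                       c("lo", "hi")),
              boot_aucs = aucs)
  })
}

# DeLong structural components: V10 (per positive) and V01 (per negative)
delong_components <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  psi <- function(x, yv) (x > yv) + 0.5 * (x == yv)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(yv) mean(psi(pos, yv)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Paired DeLong test for two correlated ROC-AUCs
#'
#' Two-sided test of equal AUC for two scores of the *same* patients, using
#' the DeLong structural-component covariance estimator. The degenerate case
#' of zero variance of the AUC difference (e.g. identical scores, or one
#' score a monotone transform of the other) returns p = 1 by convention.
#'
#' @param labels shared 0/1 outcomes.
#' @param scores_a,scores_b paired score vectors.
#' @return list with `p_value`, `auc_a`, `auc_b`, `z`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  y <- as.integer(as.logical_label(labels))
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    abort("DeLong test needs paired scores on identical patients.")
  }
  if (length(unique(y)) < 2) abort("Both classes are required.")
  ca <- delong_components(y, scores_a)
  cb <- delong_components(y, scores_b)
  m <- length(ca$v10)
  n <- length(ca$v01)
  s10 <- stats::var(cbind(ca$v10, cb$v10))
  s01 <- stats::var(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    return(list(p_value = 1, auc_a = ca$auc, auc_b = cb$auc, z = 0))
  }
  z <- (ca$auc - cb$auc) / sqrt(var_diff)
  list(p_value = 2 * pnorm(-abs(z)), auc_a = ca$auc, auc_b = cb$auc, z = z)
}

#' Combine independent p-values by Fisher's method
#'
#' `X2 = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom. Zero p-values are clipped to the smallest positive
#' double with a warning.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # ~0.0175
#' @export
fisher_combine <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  if (any(p_values == 0)) {
    warn("Zero p-value clipped to the smallest positive double.")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  x2 <- -2 * sum(log(p_values))
  pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Score threshold achieving a target specificity on derivation data
#'
#' Returns the smallest threshold (predicted positive = `score >= threshold`)
#' whose empirical specificity on the derivation data reaches the target;
#' among thresholds meeting the target this is also the one with maximal
#' sensitivity. The threshold is fixed once on derivation data and then
#' frozen for validation runs.
#'
#' @param labels,scores derivation outcomes and scores.
#' @param target target specificity (default 0.90).
#' @return a `threshold_spec` list: `threshold`, `target`,
#'   `achieved_specificity`, `achieved_sensitivity`.
#' @export
threshold_at_specificity <- function(labels, scores, target = 0.90) {
  y <- as.integer(as.logical_label(labels))
  neg <- scores[y == 0]
  if (!length(neg)) abort("Negatives are required to anchor specificity.")
  if (length(unique(scores)) == 1) {
    abort("Target specificity unattainable: all scores are equal.")
  }
  cand <- c(sort(unique(scores)), max(scores) + 1)
  spec <- vapply(cand, function(th) mean(neg < th), numeric(1))
  ok <- spec >= target
  if (!any(ok)) abort("Target specificity unattainable on these scores.")
  th <- cand[which(ok)[1]]
  structure(list(threshold = th, target = target,
                 achieved_specificity = spec[which(ok)[1]],
                 achieved_sensitivity = mean(scores[y == 1] >= th)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> score >= %.4g (target spec %.2f, achieved %.3f, sens %.3f)\n",
              x$threshold, x$target, x$achieved_specificity, x$achieved_sensitivity))
  invisible(x)
}

#' Confusion-matrix metrics at a frozen threshold
#'
#' Predicted positive is `score >= threshold`. Ratios with a zero denominator
#' (e.g. PPV with no predicted positives) are reported as `NA` with the
#' reason attached as an attribute.
#'
#' @param labels,scores outcomes and scores.
#' @param threshold frozen decision threshold (finite).
#' @return tibble with `sens`, `spec`, `ppv`, `npv`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(labels, scores, threshold) {
  stopifnot(is.finite(threshold))
  y <- as.integer(as.logical_label(labels))
  pred <- scores >= threshold
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  reasons <- character(0)
  if (tp + fn == 0) reasons <- c(reasons, "no positives: sensitivity undefined")
  if (tn + fp == 0) reasons <- c(reasons, "no negatives: specificity undefined")
  if (tp + fp == 0) reasons <- c(reasons, "no predicted positives: PPV undefined")
  if (tn + fn == 0) reasons <- c(reasons, "no predicted negatives: NPV undefined")
  structure(tibble(sens = safe_div(tp, tp + fn), spec = safe_div(tn, tn + fp),
                   ppv = safe_div(tp, tp + fp), npv = safe_div(tn, tn + fn),
                   tp = tp, fp = fp, fn = fn, tn = tn),
            missing_reason = if (length(reasons)) reasons else NULL)
}

#' Paired bootstrap test for a secondary metric difference
#'
#' Patients are resampled (stratified, with replacement) `n_boot` times; in
#' each resample the metric (sensitivity, specificity, PPV or NPV at the
#' frozen thresholds) is computed for both models and the difference
#' recorded; a two-sided one-sample t-test asks whether the bootstrap
#' distribution of differences is centred at zero. Combine across folds with
#' [fisher_combine()].
#'
#' @param labels shared outcomes.
#' @param scores_a,scores_b paired score vectors.
#' @param metric one of `"sens"`, `"spec"`, `"ppv"`, `"npv"`.
#' @param threshold_a,threshold_b frozen thresholds for the two models.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param max_undefined_frac error if the metric is undefined in more than
#'   this fraction of resamples (default 0.1).
#' @return list with `p_value`, `mean_diff`, `n_boot_used`.
#' @export
paired_bootstrap_metric_test <- function(labels, scores_a, scores_b, metric,
                                         threshold_a, threshold_b,
                                         n_boot = 1000, seed = 1,
                                         max_undefined_frac = 0.1) {
  metric <- match.arg(metric, c("sens", "spec", "ppv", "npv"))
  y <- as.integer(as.logical_label(labels))
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    abort("Paired scores on identical patients are required.")
  }
  i1 <- which(y == 1); i0 <- which(y == 0)
  with_local_seed(derive_seed(seed, paste0("pboot_", metric)), {
    diffs <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      ma <- confusion_metrics(y[idx], scores_a[idx], threshold_a)[[metric]]
      mb <- confusion_metrics(y[idx], scores_b[idx], threshold_b)[[metric]]
      ma - mb
    }, numeric(1))
    undef <- !is.finite(diffs)
    if (mean(undef) > max_undefined_frac) {
      abort(sprintf("Metric `%s` undefined in %.0f%% of resamples (limit %.0f%%).",
                    metric, 100 * mean(undef), 100 * max_undefined_frac))
    }
    d <- diffs[!undef]
    p <- if (sd(d) == 0) 1 else t.test(d)$p.value
    list(p_value = p, mean_diff = mean(d), n_boot_used = length(d))
  })
}

#' Full evaluation report for one prediction set
#'
#' ROC-AUC with a stratified bootstrap confidence interval, per-fold AUCs
#' when a `fold` column is present, and — when a frozen
#' [threshold_at_specificity()] is supplied — sensitivity, specificity, PPV
#' and NPV at that threshold.
#'
#' @param preds tibble with `label`, `prob` and optionally `fold`.
#' @param threshold_spec optional frozen `threshold_spec`.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed integer seed.
#' @return an `af_evaluation` list.
#' @export
evaluate_predictions <- function(preds, threshold_spec = NULL,
                                 n_boot = 1000, seed = 1) {
  auc <- roc_auc(preds$label, preds$prob)
  ci <- bootstrap_auc_ci(preds$label, preds$prob, n_boot = n_boot, seed = seed)
  per_fold <- NULL
  if ("fold" %in% names(preds)) {
    per_fold <- preds |>
      group_by(.data$fold) |>
      summarise(auc = roc_auc(.data$label, .data$prob), .groups = "drop")
  }
  conf <- if (!is.null(threshold_spec)) {
    confusion_metrics(preds$label, preds$prob, threshold_spec$threshold)
  } else NULL
  structure(list(auc = auc, ci = ci, per_fold = per_fold,
                 threshold_spec = threshold_spec, confusion = conf,
                 n = nrow(preds), n_pos = sum(as.logical_label(preds$label))),
            class = "af_evaluation")
}

#' @export
print.af_evaluation <- function(x, ...) {
  cat(sprintf("<af_evaluation> ROC-AUC %.3f [%.3f, %.3f] (n = %d, %d positive)\n",
              x$auc, x$ci[["lo"]], x$ci[["hi"]], x$n, x$n_pos))
  if (!is.null(x$per_fold)) {
    cat("  per-fold AUC:", paste(sprintf("%.3f", x$per_fold$auc), collapse = " "), "\n")
  }
  if (!is.null(x$confusion)) {
    cat(sprintf("  at threshold %.4g: sens %.3f spec %.3f ppv %.3f npv %.3f\n",
                x$threshold_spec$threshold, x$confusion$sens, x$confusion$spec,
                x$confusion$ppv, x$confusion$npv))
  }
  invisible(x)
}

#' Broom-style accessors for afstream result objects
#'
#' `tidy()` returns per-component detail (search log, per-fold AUCs);
#' `glance()` returns a one-row summary.
#'
#' @param x a fitted afstream object.
#' @param ... unused.
#' @return a tibble.
#' @name tidy_afstream
NULL

#' @rdname tidy_afstream
#' @method tidy af_evaluation
#' @export
tidy.af_evaluation <- function(x, ...) {
  if (is.null(x$per_fold)) {
    tibble(fold = NA_integer_, auc = x$auc)
  } else {
    x$per_fold
  }
}

#' @rdname tidy_afstream
#' @method glance af_evaluation
#' @export
glance.af_evaluation <- function(x, ...) {
  out <- tibble(auc = x$auc, ci_lo = x$ci[["lo"]], ci_hi = x$ci[["hi"]],
                n = x$n, n_pos = x$n_pos)
  if (!is.null(x$confusion)) {
    out <- bind_cols(out, select(x$confusion, "sens", "spec", "ppv", "npv"))
  }
  out
}

#' Fold-wise DeLong comparison of two models, Fisher-aggregated
#'
#' Applies the paired DeLong test within each fold (both prediction sets must
#' come from the same split plan, hence identical per-fold test patients) and
#' aggregates the per-fold p-values by Fisher's method.
#'
#' @param preds_a,preds_b prediction tibbles with `fold`, `patient_id`,
#'   `label`, `prob` from [crossval_ensemble()] (or the same shape).
#' @return list with `p_value` (combined), `per_fold` tibble.
#' @export
compare_models_delong <- function(preds_a, preds_b) {
  folds <- sort(unique(preds_a$fold))
  per_fold <- map(folds, function(f) {
    a <- filter(preds_a, .data$fold == f)
    b <- filter(preds_b, .data$fold == f)
    if (!setequal(a$patient_id, b$patient_id)) {
      abort("Fold test sets differ between models; use one shared split plan.")
    }
    b <- b[match(a$patient_id, b$patient_id), ]
    dl <- delong_test(a$label, a$prob, b$prob)
    tibble(fold = f, auc_a = dl$auc_a, auc_b = dl$auc_b, p_value = dl$p_value)
  }) |> list_rbind()
  list(p_value = fisher_combine(per_fold$p_value), per_fold = per_fold)
}
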