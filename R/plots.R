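#' ROC curve points for a set of scored patients
#'
#' @param labels 0/1 outcomes.
#' @param scores numeric scores.
#' @return tibble with `threshold`, `fpr`, `tpr`, ordered for plotting.
#' @export
roc_points <- function(labels, scores) {
  y <- as.integer(as.logical_label(labels))
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  list_rbind(map(th, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           fpr = sum(pred & y == 0) / sum(y == 0),
           tpr = sum(pred & y == 1) / sum(y == 1))
  }))
}

#' Plot the ROC curve of an evaluation report
#'
#' Requires the predictions the report was built from.
#'
#' @param object an `af_evaluation` from [evaluate_predictions()].
#' @param preds the prediction tibble (`label`, `prob`) behind the report.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot af_evaluation
#' @export
autoplot.af_evaluation <- function(object, preds, ...) {
  pts <- roc_points(preds$label, preds$prob)
  p <- ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step(linewidth = 0.8, colour = "#2166AC") +
    coord_equal() +
    labs(x = "False positive rate (1 - specificity)",
         y = "True positive rate (sensitivity)",
         title = sprintf("ROC-AUC %.3f [%.3f, %.3f]",
                         object$auc, object$ci[["lo"]], object$ci[["hi"]])) +
    theme_minimal()
  if (!is.null(object$threshold_spec) && !is.null(object$confusion)) {
    p <- p + annotate("point", x = 1 - object$confusion$spec,
                      y = object$confusion$sens, size = 3, colour = "#B2182B")
  }
  p
}

#' Plot per-fold out-of-sample ROC curves of a cross-validated model
#'
#' @param object an `af_crossval` tibble from [crossval_ensemble()].
#' @param ... unused.
#' @return a ggplot with one ROC curve per fold.
#' @method autoplot af_crossval
#' @export
autoplot.af_crossval <- function(object, ...) {
  pts <- object |>
    group_by(.data$fold) |>
    group_modify(function(df, key) roc_points(df$label, df$prob)) |>
    ungroup()
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr,
                  colour = factor(.data$fold))) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step(alpha = 0.9) +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         colour = "Fold",
         title = sprintf("Outer CV, mean ROC-AUC %.3f", glance(object)$mean_auc)) +
    theme_minimal()
}

#' Bar plot of ranked feature attributions
#'
#' @param attribution tibble from [feature_attribution()].
#' @param top_n features to display (default 15).
#' @return a ggplot.
#' @export
plot_feature_importance <- function(attribution, top_n = 15) {
  df <- head(arrange(attribution, .data$rank), top_n)
  ggplot(df, aes(x = .data$importance,
                 y = stats::reorder(.data$feature, .data$importance))) +
    geom_col(fill = "#2166AC") +
    labs(x = "Mean |attribution|", y = NULL,
         title = "Feature attribution (ranked)") +
    theme_minimal()
}

#' Tachogram plot of a beat stream
#'
#' RR interval versus time, with logged gaps shaded.
#'
#' @param object a [beat_stream()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot beat_stream
#' @export
autoplot.beat_stream <- function(object, ...) {
  df <- tibble(time_h = object$time_s / 3600, rr = beat_rr(object),
               label = object$label)
  gaps <- attr(object, "gaps")
  p <- ggplot(df, aes(x = .data$time_h, y = .data$rr)) +
    geom_point(aes(colour = .data$label), size = 0.3, alpha = 0.6) +
    scale_colour_manual(values = c(N = "grey30", S = "#E08214",
                                   V = "#B2182B", O = "grey70")) +
    labs(x = "Time since recording start (h)", y = "RR interval (ms)",
         colour = "Beat") +
    theme_minimal()
  if (nrow(gaps)) {
    p <- p + geom_rect(data = mutate(gaps, start_h = .data$start_s / 3600,
                                     end_h = .data$end_s / 3600),
                       aes(xmin = .data$start_h, xmax = .data$end_h,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15, fill = "#2166AC")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
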