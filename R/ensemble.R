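#' Train an ensemble AF classifier by randomized search with inner CV
#'
#' The model family and its hyperparameters are chosen by randomized search
#' over three candidate families — regularized logistic regression
#' (`glmnet`), random forest (`ranger`) and gradient boosting (`xgboost`) —
#' each candidate scored by mean ROC-AUC under stratified `inner_k`-fold
#' cross-validation *inside the training data*; the winner is refit on the
#' full training data. Median imputation statistics and class weights are
#' computed on the training data only, so no information leaks from any test
#' fold. Identical data + seed give identical fits (all learners run
#' single-threaded with fixed seeds).
#'
#' @param features data frame of predictors; non-numeric columns except
#'   `sex` (encoded 0/1) are dropped, as is `patient_id`.
#' @param labels vector of outcomes, length `nrow(features)` (0/1, logical,
#'   or AF label strings).
#' @param search_budget number of random candidates (default 6).
#' @param inner_k inner CV folds (default 3).
#' @param seed integer seed.
#' @return an object of class `af_ensemble` with the fitted winner, its
#'   search log, the feature schema and the stored imputation medians.
#' @export
train_ensemble <- function(features, labels, search_budget = 6, inner_k = 3, seed = 1) {
  x <- encode_features(features)
  y <- as.integer(as.logical_label(labels))
  if (length(unique(y)) < 2) abort("Training fold contains a single class; refusing to fit.")
  if (nrow(x) != length(y)) abort("`features` and `labels` sizes differ.")
  medians <- vapply(x, function(col) median(col, na.rm = TRUE), numeric(1))
  x <- impute_medians(x, medians)
  with_local_seed(derive_seed(seed, "ensemble_search"), {
    candidates <- map(seq_len(search_budget), function(i) draw_candidate())
    inner <- stratified_folds(y, inner_k)
    scores <- map_dbl(candidates, function(cand) {
      aucs <- map_dbl(seq_len(inner_k), function(k) {
        tr <- inner != k
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) return(NA_real_)
        fit <- fit_candidate(x[tr, , drop = FALSE], y[tr], cand)
        roc_auc(y[!tr], predict_candidate(fit, x[!tr, , drop = FALSE]))
      })
      mean(aucs, na.rm = TRUE)
    })
    best <- which.max(scores)
    final <- fit_candidate(x, y, candidates[[best]])
    structure(list(
      kind = "ensemble",
      candidate = candidates[[best]],
      fit = final,
      medians = medians,
      schema = names(x),
      search_log = tibble(
        candidate = seq_along(candidates),
        family = map_chr_local(candidates, "family"),
        inner_auc = scores
      ),
      seed = seed
    ), class = "af_ensemble")
  })
}

map_chr_local <- function(x, field) vapply(x, function(e) as.character(e[[field]]), character(1))

# numeric design matrix (tibble) from a feature data frame
encode_features <- function(features) {
  x <- as_tibble(features)
  x <- select(x, -any_of(c("patient_id", "label", "hours_used", "n_segments_used",
                           "missing_reason")))
  if ("sex" %in% names(x)) x$sex <- as.numeric(x$sex %in% c("male", "1", "TRUE"))
  x <- mutate(x, across(where(is.logical), as.numeric))
  keep <- vapply(x, is.numeric, logical(1))
  x[, keep, drop = FALSE]
}

impute_medians <- function(x, medians) {
  for (nm in names(medians)) {
    miss <- is.na(x[[nm]])
    if (any(miss)) x[[nm]][miss] <- medians[[nm]]
  }
  x
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

draw_candidate <- function() {
  family <- sample(c("glmnet", "ranger", "xgboost"), 1)
  switch(family,
    glmnet = list(family = "glmnet",
                  alpha = runif(1),
                  lambda = 10^runif(1, -4, -0.5)),
    ranger = list(family = "ranger",
                  num_trees = sample(c(150L, 300L), 1),
                  mtry_frac = runif(1, 0.2, 0.8),
                  min_node = sample(c(1L, 5L, 10L), 1),
                  seed = sample.int(1e6, 1)),
    xgboost = list(family = "xgboost",
                   eta = runif(1, 0.03, 0.3),
                   max_depth = sample(2:5, 1),
                   nrounds = sample(c(50L, 100L, 150L), 1),
                   subsample = runif(1, 0.6, 1),
                   colsample = runif(1, 0.5, 1),
                   min_child = sample(c(1, 3, 5), 1),
                   seed = sample.int(1e6, 1))
  )
}

fit_candidate <- function(x, y, cand) {
  xm <- as.matrix(x)
  w <- ifelse(y == 1, length(y) / (2 * sum(y == 1)), length(y) / (2 * sum(y == 0)))
  model <- switch(cand$family,
    glmnet = glmnet::glmnet(xm, y, family = "binomial", weights = w,
                            alpha = cand$alpha, lambda = cand$lambda,
                            standardize = TRUE),
    ranger = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = cand$num_trees,
      mtry = max(1L, floor(cand$mtry_frac * ncol(x))),
      min.node.size = cand$min_node,
      case.weights = w, seed = cand$seed, num.threads = 1,
      verbose = FALSE),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = cand$eta,
                    max_depth = cand$max_depth, subsample = cand$subsample,
                    colsample_bytree = cand$colsample,
                    min_child_weight = cand$min_child,
                    nthread = 1, seed = cand$seed,
                    eval_metric = "logloss"),
      data = xgboost::xgb.DMatrix(xm, label = y, weight = w),
      nrounds = cand$nrounds, verbose = 0)
  )
  list(cand = cand, model = model)
}

predict_candidate <- function(fit, x) {
  xm <- as.matrix(x)
  p <- switch(fit$cand$family,
    glmnet = as.numeric(predict(fit$model, xm, type = "response")),
    ranger = predict(fit$model, data = x, num.threads = 1)$predictions[, "1"],
    xgboost = predict(fit$model, xgboost::xgb.DMatrix(xm))
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Predict AF probabilities from a fitted ensemble
#'
#' Missing feature values are imputed with the medians stored at training
#' time. The feature schema must match the training schema.
#'
#' @param object an `af_ensemble`.
#' @param newdata data frame of predictors.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.af_ensemble <- function(object, newdata, ...) {
  x <- encode_features(newdata)
  missing_cols <- setdiff(object$schema, names(x))
  extra_cols <- setdiff(names(x), object$schema)
  if (length(missing_cols) || length(extra_cols)) {
    abort(sprintf("Feature schema mismatch. Missing: %s. Unexpected: %s.",
                  paste(missing_cols, collapse = ", "),
                  paste(extra_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(numeric(0))
  x <- impute_medians(x[, object$schema, drop = FALSE], object$medians)
  predict_candidate(object$fit, x)
}

#' @export
print.af_ensemble <- function(x, ...) {
  cat(sprintf("<af_ensemble> winner: %s (inner ROC-AUC %.3f), %d features\n",
              x$candidate$family, max(x$search_log$inner_auc, na.rm = TRUE),
              length(x$schema)))
  invisible(x)
}

#' @rdname tidy_afstream
#' @method tidy af_ensemble
#' @export
tidy.af_ensemble <- function(x, ...) {
  x$search_log
}

#' @rdname tidy_afstream
#' @method glance af_ensemble
#' @export
glance.af_ensemble <- function(x, ...) {
  tibble(family = x$candidate$family,
         n_features = length(x$schema),
         inner_auc = max(x$search_log$inner_auc, na.rm = TRUE),
         n_candidates = nrow(x$search_log))
}

#' Outer cross-validation of an ensemble model under a shared split plan
#'
#' Trains one ensemble per fold on the fold's training patients and predicts
#' the fold's test patients, giving the out-of-sample probabilities that the
#' fusion and evaluation layers consume.
#'
#' @param features tibble with a `patient_id` column plus predictors.
#' @param labels tibble with `patient_id` and `label`.
#' @param plan a [make_patient_splits()] plan built from the same labels.
#' @param search_budget,inner_k,seed passed to [train_ensemble()].
#' @return an `af_crossval` object: tibble of predictions (`fold`,
#'   `patient_id`, `label`, `prob`) with the per-fold fitted models in
#'   attribute `models`.
#' @export
crossval_ensemble <- function(features, labels, plan,
                              search_budget = 6, inner_k = 3, seed = 1) {
  stopifnot(all(c("patient_id") %in% names(features)))
  lab <- setNames(as.integer(as.logical_label(labels$label)), labels$patient_id)
  models <- vector("list", nrow(plan))
  preds <- map(seq_len(nrow(plan)), function(f) {
    tr_ids <- plan$train[[f]]
    te_ids <- plan$test[[f]]
    tr <- features[match(tr_ids, features$patient_id), , drop = FALSE]
    te <- features[match(te_ids, features$patient_id), , drop = FALSE]
    fit <- train_ensemble(tr, lab[tr_ids], search_budget = search_budget,
                          inner_k = inner_k, seed = derive_seed(seed, paste0("fold", f)))
    models[[f]] <<- fit
    tibble(fold = f, patient_id = te_ids, label = unname(lab[te_ids]),
           prob = predict(fit, te))
  })
  out <- list_rbind(preds)
  structure(out, models = models, class = c("af_crossval", class(out)))
}

#' @rdname tidy_afstream
#' @method glance af_crossval
#' @export
glance.af_crossval <- function(x, ...) {
  per_fold <- x |>
    group_by(.data$fold) |>
    summarise(auc = roc_auc(.data$label, .data$prob), .groups = "drop")
  tibble(mean_auc = mean(per_fold$auc),
         sd_auc = sd(per_fold$auc),
         n_folds = nrow(per_fold),
         n_patients = length(unique(x$patient_id)))
}

#' @rdname tidy_afstream
#' @method tidy af_crossval
#' @export
tidy.af_crossval <- function(x, ...) {
  x |>
    group_by(.data$fold) |>
    summarise(auc = roc_auc(.data$label, .data$prob),
              n_test = dplyr::n(), n_pos = sum(.data$label), .groups = "drop")
}
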