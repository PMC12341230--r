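synthetic_feature_set <- function(n = 120, p_noise = 3, effect = 2, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.3)
  df <- tibble::tibble(patient_id = sprintf("p%03d", seq_len(n)),
                       signal = rnorm(n, y * effect),
                       age = rnorm(n, 70 + 4 * y, 10))
  for (j in seq_len(p_noise)) df[[paste0("noise", j)]] <- rnorm(n)
  list(features = df, labels = tibble::tibble(patient_id = df$patient_id, label = y))
}

test_that("stratified shuffle splits have the advertised shape", {
  labs <- tibble::tibble(patient_id = sprintf("p%03d", 1:100),
                         label = rep(c(1, 0), c(10, 90)))
  plan <- make_patient_splits(labs, seed = 3)
  expect_equal(nrow(plan), 5)
  for (f in 1:5) {
    expect_length(plan$test[[f]], 20)
    expect_equal(sum(plan$test[[f]] %in% labs$patient_id[labs$label == 1]), 2)
    expect_length(intersect(plan$train[[f]], plan$test[[f]]), 0)
    expect_setequal(c(plan$train[[f]], plan$test[[f]]), labs$patient_id)
  }
  expect_identical(make_patient_splits(labs, seed = 3), plan)
  tiny <- tibble::tibble(patient_id = c("a", "b", "c"), label = c(1, 0, 0))
  expect_error(make_patient_splits(tiny), "at least 2 patients")
})

test_that("ensemble training is deterministic and leak-free", {
  d <- synthetic_feature_set()
  fit1 <- train_ensemble(d$features, d$labels$label, search_budget = 4, seed = 11)
  fit2 <- train_ensemble(d$features, d$labels$label, search_budget = 4, seed = 11)
  p1 <- predict(fit1, d$features)
  expect_identical(p1, predict(fit2, d$features))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(nrow(fit1$search_log), 4)
  # imputation medians come from the training rows only
  dd <- d$features
  dd$signal[1:10] <- NA
  fit3 <- train_ensemble(dd, d$labels$label, search_budget = 2, seed = 1)
  expect_equal(unname(fit3$medians["signal"]),
               median(dd$signal, na.rm = TRUE))
  expect_error(train_ensemble(d$features, rep(1, nrow(d$features))),
               "single class")
  expect_error(predict(fit1, dplyr::select(d$features, -"signal")),
               "schema mismatch")
  expect_length(predict(fit1, d$features[0, ]), 0)
})

test_that("cross-validated predictions separate a planted signal", {
  d <- synthetic_feature_set(n = 150, effect = 2.5, seed = 5)
  plan <- make_patient_splits(d$labels, seed = 5)
  cv <- crossval_ensemble(d$features, d$labels, plan, search_budget = 4, seed = 5)
  expect_setequal(unique(cv$fold), 1:5)
  expect_gt(glance(cv)$mean_auc, 0.8)
  # fold test sets follow the plan exactly
  for (f in 1:5) {
    expect_setequal(cv$patient_id[cv$fold == f], plan$test[[f]])
  }
})

test_that("rising age does not lower final-model risk on average", {
  feats <- shared_cohort_features()
  labs <- af_labels(shared_cohort())
  fit <- train_ensemble(feats, labs$label[match(feats$patient_id, labs$patient_id)],
                        search_budget = 4, seed = 21)
  probe <- feats[rep(1, 13), ]
  probe[hrv_feature_registry()] <- lapply(feats[hrv_feature_registry()],
                                          function(col) median(col, na.rm = TRUE))
  probe$age <- seq(55, 91, by = 3)
  p <- predict(fit, probe)
  expect_gte(mean(diff(p)), -1e-6)
})

make_cnn_fixture <- function(per_pat = 8, n_pat = 40, seed = 33) {
  set.seed(seed)
  make_trace <- function(irregular) {
    rr <- if (irregular) runif(8, 0.45, 1.0) else rnorm(8, 0.8, 0.03)
    t <- runif(1, 0, 0.6) + cumsum(rr)
    x <- rnorm(2560, 0, 0.05)
    for (tt in t[t < 5.0]) {
      idx <- round(tt * 500)
      win <- max(1, idx - 10):min(2560, idx + 10)
      x[win] <- x[win] + exp(-0.5 * ((win - idx) / 4)^2)
      if (!irregular) {  # P wave present only in the regular class
        pidx <- idx - 90
        if (pidx > 15) {
          pw <- (pidx - 10):(pidx + 10)
          x[pw] <- x[pw] + 0.15 * exp(-0.5 * ((pw - pidx) / 6)^2)
        }
      }
    }
    x
  }
  n_pos <- n_pat / 2 * per_pat
  list(
    segs = tibble::tibble(
      patient_id = rep(sprintf("p%03d", seq_len(n_pat)), each = per_pat),
      samples = c(lapply(seq_len(n_pat * per_pat), function(i) make_trace(i <= n_pos)))
    ),
    y = rep(c(1, 0), each = n_pos),
    train_ids = sprintf("p%03d", c(1:12, (n_pat / 2 + 1):(n_pat / 2 + 12)))
  )
}

test_that("the CNN learns separable traces and degrades to chance on shuffled labels", {
  fx <- make_cnn_fixture()
  tr <- fx$segs$patient_id %in% fx$train_ids
  fit <- train_cnn(fx$segs[tr, ], fx$y[tr], epochs = 20, lr = 0.003, seed = 2)
  fit_b <- train_cnn(fx$segs[tr, ], fx$y[tr], epochs = 20, lr = 0.003, seed = 2)
  expect_identical(fit$losses, fit_b$losses)        # deterministic
  auc <- roc_auc(fx$y[!tr], predict(fit, fx$segs[!tr, ]))
  expect_gt(auc, 0.7)
  # label-shuffled training: held-out AUC is chance on average over shuffles
  null_aucs <- vapply(1:6, function(s) {
    set.seed(s)
    fit_null <- train_cnn(fx$segs[tr, ], sample(fx$y[tr]),
                          epochs = 20, lr = 0.003, seed = 100 + s)
    roc_auc(fx$y[!tr], predict(fit_null, fx$segs[!tr, ]))
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.15)
  expect_error(train_cnn(fx$segs[1:16, ], rep(c(0, 1), c(4, 12)), seed = 1),
               "per class")
})

test_that("segment aggregation averages k sampled segment probabilities", {
  preds <- tibble::tibble(patient_id = rep(c("a", "b"), c(4, 1)),
                          prob = c(0.7, 0.7, 0.7, 0.7, 0.4))
  agg_all <- aggregate_segment_predictions(preds, k = 10, seed = 1)
  expect_equal(agg_all$prob[agg_all$patient_id == "a"], 0.7)
  expect_equal(agg_all$n_segments_used, c(4L, 1L))
  agg1 <- aggregate_segment_predictions(preds, k = 1, seed = 2)
  expect_true(agg1$prob[agg1$patient_id == "a"] %in% preds$prob[preds$patient_id == "a"])
  expect_warning(aggregate_segment_predictions(preds[0, ], k = 1), "No segment")
})

test_that("additive attribution satisfies additivity and finds planted signal", {
  d <- synthetic_feature_set(n = 200, effect = 3, seed = 9)
  fit <- train_ensemble(d$features, d$labels$label, search_budget = 3, seed = 9)
  att <- feature_attribution(fit, d$features, method = "shap", n_rows = 25, seed = 9)
  phi <- attr(att, "shap_values")
  base <- attr(att, "baseline")
  x <- afstream:::encode_features(d$features)
  x <- afstream:::impute_medians(x[, fit$schema, drop = FALSE], fit$medians)
  preds <- afstream:::predict_candidate(fit$fit, x)[attr(att, "rows")]
  expect_equal(unname(rowSums(phi)), preds - base, tolerance = 1e-8)
  expect_equal(att$feature[1], "signal")
  perm <- feature_attribution(fit, d$features, method = "permutation",
                              labels = d$labels$label, seed = 9)
  expect_equal(perm$feature[1], "signal")
  expect_true(all(c("noise1", "noise2", "noise3") %in%
                    perm$feature[(nrow(perm) - 3):nrow(perm)]))
})
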