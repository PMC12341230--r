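test_that("rank ROC-AUC equals brute-force concordance", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2)), 1.0)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  set.seed(21)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.15, 0.5))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n), sample(c(1, 2, 8), 1))  # some heavy-tie cases
    expect_equal(roc_auc(y, s), oracle_auc(y, s), tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(22)
  y <- rbinom(80, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(80)
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a, tolerance = 1e-12)
  expect_equal(roc_auc(y, 3 * s - 10), a, tolerance = 1e-12)
})

test_that("stratified bootstrap CI is reproducible and collapses when perfect", {
  set.seed(23)
  y <- rep(c(1, 0), each = 150)
  s <- c(rnorm(150, 3), rnorm(150, 0))
  ci1 <- bootstrap_auc_ci(y, s, n_boot = 200, seed = 5)
  ci2 <- bootstrap_auc_ci(y, s, n_boot = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(ci1[["lo"]] <= ci1[["hi"]])
  perfect <- bootstrap_auc_ci(y, y + rnorm(300, 0, 1e-9), n_boot = 200, seed = 1)
  expect_gt(perfect[["lo"]], 0.99)
})

test_that("DeLong test handles degenerate and transformed scores by convention", {
  set.seed(24)
  y <- rbinom(100, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(100)
  expect_equal(delong_test(y, s, s)$p_value, 1)
  expect_equal(delong_test(y, s, exp(s))$p_value, 1)
  expect_error(delong_test(y, s, s[-1]), "paired")
})

test_that("DeLong p-values agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  for (i in 1:30) {
    n <- sample(40:120, 1)
    y <- rbinom(n, 1, 0.4); y[1:2] <- c(0, 1)
    base <- rnorm(n) + y
    sa <- base + rnorm(n, 0, 0.8)
    sb <- base + rnorm(n, 0, 0.8)
    ours <- delong_test(y, sa, sb)$p_value
    ref <- suppressMessages(pROC::roc.test(
      pROC::roc(y, sa, quiet = TRUE), pROC::roc(y, sb, quiet = TRUE),
      method = "delong"))$p.value
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("Fisher combination matches the chi-square closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(-2 * 2 * log(0.05), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  for (p in c(0.01, 0.2, 0.7)) {
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)  # df-2 identity
  }
  expect_warning(out <- fisher_combine(c(0, 0.5)), "clipped")
  expect_true(out > 0)
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
})

test_that("specificity-anchored threshold follows the order statistics", {
  y <- rep(0, 10)
  s <- seq(0, 0.9, by = 0.1)
  th <- threshold_at_specificity(c(y, 1), c(s, 0.95), target = 0.9)
  expect_equal(th$threshold, 0.9)
  expect_equal(th$achieved_specificity, 0.9)
  th100 <- threshold_at_specificity(c(y, 1), c(s, 0.95), target = 1.0)
  expect_gt(th100$threshold, 0.9)
  expect_equal(th100$achieved_specificity, 1.0)
  expect_error(threshold_at_specificity(c(0, 0, 1), rep(0.4, 3), target = 0.9),
               "unattainable")
  # contract: achieved specificity >= target on derivation data, max sensitivity
  set.seed(26)
  for (i in 1:20) {
    yy <- rbinom(200, 1, 0.2); yy[1:2] <- c(0, 1)
    ss <- rnorm(200) + yy
    tt <- threshold_at_specificity(yy, ss, 0.9)
    expect_gte(tt$achieved_specificity, 0.9)
    cheaper <- max(ss[yy == 0][ss[yy == 0] < tt$threshold])
    expect_lt(mean(ss[yy == 0] < cheaper), 0.9)  # next lower threshold fails
  }
})

test_that("confusion metrics reproduce the validation-regime arithmetic", {
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 0.5)
  expect_equal(unlist(perfect[c("sens", "spec", "ppv", "npv")]),
               c(sens = 1, spec = 1, ppv = 1, npv = 1))
  # TP 14, FP 149, FN 22, TN 1334 — low-prevalence validation regime
  y <- rep(c(1, 1, 0, 0), c(14, 22, 149, 1334))
  s <- rep(c(1, 0, 1, 0), c(14, 22, 149, 1334))
  cm <- confusion_metrics(y, s, 0.5)
  expect_equal(cm$sens, 14 / 36, tolerance = 1e-12)
  expect_equal(cm$ppv, 14 / 163, tolerance = 1e-12)
  expect_equal(cm$npv, 1334 / 1356, tolerance = 1e-12)
  none_pos <- confusion_metrics(c(1, 0, 0), c(0.1, 0.2, 0.3), 0.9)
  expect_true(is.na(none_pos$ppv))
  expect_false(is.na(none_pos$npv))
  expect_match(attr(none_pos, "missing_reason"), "PPV", all = FALSE)
})

test_that("paired bootstrap metric test is calibrated and powered", {
  set.seed(27)
  y <- rbinom(300, 1, 0.2); y[1:2] <- c(0, 1)
  s <- rnorm(300) + y
  same <- paired_bootstrap_metric_test(y, s, s, "sens", 0.5, 0.5,
                                       n_boot = 200, seed = 3)
  expect_gt(same$p_value, 0.99)
  s_alt <- s + rnorm(300, 0, 0.3)
  expect_identical(
    paired_bootstrap_metric_test(y, s, s_alt, "sens", 0.5, 0.6,
                                 n_boot = 100, seed = 4),
    paired_bootstrap_metric_test(y, s, s_alt, "sens", 0.5, 0.6,
                                 n_boot = 100, seed = 4))
  # planted sensitivity gap at the validation regime's scale
  set.seed(28)
  n <- 1500
  yy <- rbinom(n, 1, 0.02); yy[1:2] <- c(0, 1)
  sa <- ifelse(yy == 1, rbinom(n, 1, 0.4), rbinom(n, 1, 0.1))
  sb <- ifelse(yy == 1, rbinom(n, 1, 0.05), rbinom(n, 1, 0.1))
  gap <- paired_bootstrap_metric_test(yy, sa, sb, "sens", 0.5, 0.5,
                                      n_boot = 500, seed = 5)
  expect_lt(gap$p_value, 0.01)
  expect_gt(gap$mean_diff, 0)
})

test_that("evaluation report and model comparison wire the pieces together", {
  set.seed(29)
  n <- 200
  y <- rbinom(n, 1, 0.25); y[1:2] <- c(0, 1)
  preds <- tibble::tibble(patient_id = sprintf("p%03d", 1:n),
                          fold = rep(1:5, each = 40),
                          label = y, prob = plogis(y + rnorm(n)))
  th <- threshold_at_specificity(preds$label, preds$prob, 0.9)
  ev <- evaluate_predictions(preds, th, n_boot = 200, seed = 6)
  expect_true(ev$ci[["lo"]] <= ev$auc && ev$auc <= ev$ci[["hi"]])
  expect_equal(nrow(ev$per_fold), 5)
  g <- glance(ev)
  expect_true(all(c("auc", "sens", "spec") %in% names(g)))
  preds_b <- dplyr::mutate(preds, prob = plogis(label + rnorm(n)))
  cmp <- compare_models_delong(preds, preds_b)
  expect_equal(nrow(cmp$per_fold), 5)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  bad <- dplyr::mutate(preds_b, patient_id = rev(preds_b$patient_id))
  expect_error(compare_models_delong(preds, bad), "shared split plan|differ")
})

test_that("identical-scores paired-metric resamples count as agreement, not failure", {
  # regression guard: sd of all-zero differences must not divide by zero
  y <- rep(c(1, 0), each = 30)
  s <- seq_len(60)
  out <- paired_bootstrap_metric_test(y, s, s, "spec", 30, 30, n_boot = 50, seed = 1)
  expect_equal(out$p_value, 1)
})
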