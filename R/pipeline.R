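#' Patient-level model inputs from a cohort
#'
#' `cohort_hrv_features()` runs the full beat-stream pipeline for every
#' patient — AF excision with buffer, beat cleaning, short-gap interpolation,
#' 5-minute segmentation, the 19-feature HRV bank, restriction to the first
#' `hours` of monitoring and hourly aggregation — and returns one row per
#' patient. `final_model_features()` appends age, giving the input of the
#' final simplified model (age + first-hour HRV).
#'
#' @param cohort tibble from [simulate_cohort()] (or the same shape built
#'   from [read_beat_csv()]/[read_alarm_csv()] files).
#' @param hours HRV observation window from recording start (default 1).
#' @param buffer_s AF excision buffer, seconds.
#' @param max_gap_s gap-interpolation threshold, seconds.
#' @return tibble: `patient_id`, HRV feature columns, `hours_used`,
#'   `n_segments_used` (plus `age` for `final_model_features()`).
#' @export
cohort_hrv_features <- function(cohort, hours = 1, buffer_s = 150, max_gap_s = 3) {
  segs <- map2(cohort$beats, cohort$af, function(bs, af) {
    preprocess_stream(bs, af, buffer_s = buffer_s, max_gap_s = max_gap_s)
  }) |> list_rbind()
  segs <- restrict_first_hours(segs, hours)
  feats <- hrv_features(segs)
  hourly_aggregate(feats)
}

#' @rdname cohort_hrv_features
#' @export
final_model_features <- function(cohort, hours = 1, buffer_s = 150, max_gap_s = 3) {
  hrv <- cohort_hrv_features(cohort, hours = hours, buffer_s = buffer_s,
                             max_gap_s = max_gap_s)
  left_join(hrv, select(cohort, "patient_id", "age"), by = "patient_id") |>
    relocate("age", .after = "patient_id")
}

#' AF outcome labels of a cohort
#'
#' @param cohort tibble with `patient_id` and `label`
#'   (`no_af`/`ndaf`/`known_af`).
#' @param include_known_af count pre-known AF as positive (default TRUE;
#'   irrelevant when the cohort has no `known_af` patients).
#' @return tibble `patient_id`, `label` (0/1).
#' @export
af_labels <- function(cohort, include_known_af = TRUE) {
  pos <- if (include_known_af) c("ndaf", "known_af") else "ndaf"
  tibble(patient_id = cohort$patient_id,
         label = as.integer(cohort$label %in% pos))
}

#' Run the final simplified model (age + first-hour HRV) on a cohort
#'
#' Builds the final-model feature matrix, the patient-level stratified
#' shuffle-split plan, and the outer cross-validated ensemble predictions.
#'
#' @param cohort tibble from [simulate_cohort()].
#' @param hours HRV window (default 1).
#' @param n_splits,test_frac split-plan parameters (defaults 5 and 0.2).
#' @param search_budget,inner_k ensemble search parameters.
#' @param seed integer seed for splits and model fits.
#' @return list with `preds` (an `af_crossval` tibble), `features`,
#'   `labels`, `plan`.
#' @export
run_final_model <- function(cohort, hours = 1, n_splits = 5, test_frac = 0.2,
                            search_budget = 6, inner_k = 3, seed = 1) {
  features <- final_model_features(cohort, hours = hours)
  labels <- af_labels(cohort)
  labels <- labels[match(features$patient_id, labels$patient_id), ]
  plan <- make_patient_splits(labels, n_splits = n_splits,
                              test_frac = test_frac, seed = seed)
  preds <- crossval_ensemble(features, labels, plan,
                             search_budget = search_budget,
                             inner_k = inner_k, seed = seed)
  list(preds = preds, features = features, labels = labels, plan = plan)
}

#' Leakage-free derivation scores of one fixed model configuration
#'
#' Refits the *winning* configuration of a fitted ensemble on k stratified
#' folds of the derivation data and returns out-of-fold probabilities. Use
#' this to anchor a decision threshold on the derivation cohort for a model
#' that will be deployed after refitting on all derivation data: every score
#' (derivation and validation) then comes from the same model family and
#' hyperparameters, so the score scale — and with it the frozen threshold —
#' is comparable across cohorts.
#'
#' @param model a fitted `af_ensemble` (its `candidate` is reused; no new
#'   hyperparameter search happens here).
#' @param features derivation feature rows (same schema as at training).
#' @param labels derivation outcomes.
#' @param k cross-fitting folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return numeric vector of out-of-fold probabilities, aligned to rows.
#' @export
cross_fitted_scores <- function(model, features, labels, k = 5, seed = 1) {
  x <- encode_features(features)
  x <- impute_medians(x[, model$schema, drop = FALSE], model$medians)
  y <- as.integer(as.logical_label(labels))
  with_local_seed(derive_seed(seed, "crossfit"), {
    fold <- stratified_folds(y, k)
    out <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- fit_candidate(x[tr, , drop = FALSE], y[tr], model$candidate)
      out[!tr] <- predict_candidate(fit, x[!tr, , drop = FALSE])
    }
    out
  })
}
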