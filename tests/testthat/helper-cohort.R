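# A small cohort shared across modeling-oriented tests, built once per run.
.test_cache <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.test_cache$cohort)) {
    .test_cache$cohort <- simulate_cohort(
      cohort_config(n_patients = 40, af_prevalence = 0.3,
                    monitoring_hours = 1.25, seed = 424242)
    )
  }
  .test_cache$cohort
}

shared_cohort_features <- function() {
  if (is.null(.test_cache$features)) {
    .test_cache$features <- final_model_features(shared_cohort(), hours = 1)
  }
  .test_cache$features
}
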