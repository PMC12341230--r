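#' Default effect sizes separating AF-prone from control patients
#'
#' Group contrasts applied by the cohort generator, all expressed relative to
#' the control (no-AF) phenotype:
#' * `rmssd_ratio` (> 1): multiplier on the HF and broadband RR modulation
#'   amplitudes, raising short-term beat-to-beat variability.
#' * `dfa_alpha1_shift` (< 0): target shift of the short-scale DFA exponent,
#'   implemented as a `2 * shift` change of the noise spectral slope (for
#'   `1/f^beta` noise the DFA exponent is approximately `(beta + 1) / 2`).
#' * `sves_rate_ratio` (> 1): multiplier on the supraventricular ectopy rate.
#' * `age_shift_years` (> 0): additive age contrast; the default 8.3 years
#'   reproduces the direction and rough magnitude of the age gap reported
#'   for stroke-unit cohorts (mean age 79.2 vs 70.9 years in AF versus
#'   non-AF groups).
#' * `short_run_rate`: short atrial runs per hour in AF-prone patients.
#'
#' @param rmssd_ratio,dfa_alpha1_shift,sves_rate_ratio,age_shift_years,short_run_rate
#'   see above.
#' @return named list of effect sizes.
#' @export
cohort_effect_sizes <- function(rmssd_ratio = 1.5,
                                dfa_alpha1_shift = -0.15,
                                sves_rate_ratio = 3,
                                age_shift_years = 8.3,
                                short_run_rate = 2) {
  stopifnot(rmssd_ratio > 0, sves_rate_ratio > 0, age_shift_years >= 0,
            dfa_alpha1_shift <= 0, short_run_rate >= 0)
  list(rmssd_ratio = rmssd_ratio, dfa_alpha1_shift = dfa_alpha1_shift,
       sves_rate_ratio = sves_rate_ratio, age_shift_years = age_shift_years,
       short_run_rate = short_run_rate)
}

clip_num <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample one patient's clinical covariates
#'
#' Draws the clinical vector (age, sex, NIHSS, mRS, vascular comorbidity
#' flags, log-troponin, GFR) from parametric distributions whose group
#' contrasts follow the direction and rough magnitude of a stroke-unit
#' derivation cohort: AF patients are older, more severely affected (higher
#' NIHSS and mRS) and more often have heart failure. All fields are populated;
#' set `missing_rate > 0` to blank laboratory values at random for
#' exclusion-logic tests.
#'
#' @param label one of `"no_af"`, `"ndaf"`, `"known_af"`.
#' @param effect_sizes a [cohort_effect_sizes()] list.
#' @param seed integer seed.
#' @param missing_rate probability that `log_troponin`/`gfr` are missing.
#' @return one-row tibble of clinical covariates.
#' @export
sample_clinical_features <- function(label,
                                     effect_sizes = cohort_effect_sizes(),
                                     seed = 1,
                                     missing_rate = 0) {
  label <- match.arg(label, c("no_af", "ndaf", "known_af"))
  afp <- label != "no_af"
  with_local_seed(derive_seed(seed, paste0("clinical_", label)), {
    age <- clip_num(rnorm(1, 70.9 + afp * effect_sizes$age_shift_years,
                          if (afp) 9.0 else 13.4), 25, 102)
    nihss <- clip_num(rnbinom(1, size = if (afp) 1.2 else 0.8,
                              mu = if (afp) 6.7 else 2.9), 0, 42)
    mrs <- rbinom(1, 6, if (afp) 2.9 / 6 else 1.7 / 6)
    out <- tibble(
      age = age,
      sex = if (rbinom(1, 1, if (afp) 0.524 else 0.465) == 1) "female" else "male",
      nihss = as.integer(nihss),
      mrs = as.integer(mrs),
      ica_stenosis_gt50 = rbinom(1, 1, if (afp) 0.049 else 0.063) == 1,
      hypertension = rbinom(1, 1, if (afp) 0.767 else 0.742) == 1,
      diabetes = rbinom(1, 1, if (afp) 0.252 else 0.217) == 1,
      heart_failure = rbinom(1, 1, if (afp) 0.155 else 0.083) == 1,
      cad = rbinom(1, 1, if (afp) 0.155 else 0.186) == 1,
      log_troponin = rnorm(1, 2.3 + afp * 0.4, 0.9),
      gfr = clip_num(rnorm(1, if (afp) 65 else 72, 18), 5, 150)
    )
    if (missing_rate > 0) {
      if (runif(1) < missing_rate) out$log_troponin <- NA_real_
      if (runif(1) < missing_rate) out$gfr <- NA_real_
    }
    out
  })
}
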