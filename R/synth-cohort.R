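#' Configuration of a synthetic stroke-unit monitoring cohort
#'
#' Bundles everything that determines a generated cohort. The configuration
#' plus the seed fully determine the output; each patient draws from an RNG
#' stream derived from `(seed, patient_id)` so cohorts are reproducible under
#' any generation order.
#'
#' @param n_patients number of patients (>= 2).
#' @param af_prevalence probability that a patient is labelled `ndaf`
#'   (newly detected AF); default 0.06, the derivation-cohort rate.
#' @param known_af_fraction probability of a `known_af` label (default 0; the
#'   primary analysis excludes pre-known AF).
#' @param monitoring_hours monitored duration per patient (default 72).
#' @param dropout list with `rate_per_hour`, `mean_s`, `min_s` describing
#'   monitoring interruptions (see [insert_monitoring_gaps()]).
#' @param effect_sizes a [cohort_effect_sizes()] list.
#' @param base latent control phenotype: `mean_rr`/`mean_rr_sd` (ms),
#'   `lf_amp`, `hf_amp`, `noise_amp` (ms), `noise_beta`, hourly `sves_rate`,
#'   `ves_rate` and `short_run_rate`, plus AF-episode parameters
#'   `af_episode_rate` (per hour, labelled patients only) and
#'   `af_episode_mean_s`. Between-patient variability multiplies the
#'   modulation amplitudes by a lognormal factor with `sdlog = pheno_sdlog`.
#' @param sampling_rate raw-ECG sampling rate, Hz (default 500).
#' @param seed integer master seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100,
                          af_prevalence = 0.06,
                          known_af_fraction = 0,
                          monitoring_hours = 72,
                          dropout = list(rate_per_hour = 0.15, mean_s = 600, min_s = 60),
                          effect_sizes = cohort_effect_sizes(),
                          base = list(mean_rr = 850, mean_rr_sd = 70,
                                      lf_amp = 25, hf_amp = 20,
                                      noise_amp = 20, noise_beta = 1,
                                      sves_rate = 5, ves_rate = 3,
                                      short_run_rate = 0.1,
                                      af_episode_rate = 1, af_episode_mean_s = 90,
                                      pheno_sdlog = 0.2),
                          sampling_rate = 500,
                          seed = 20220101) {
  if (n_patients < 2) abort("`n_patients` must be >= 2.")
  if (af_prevalence <= 0 || af_prevalence >= 1) abort("`af_prevalence` must be in (0, 1).")
  if (monitoring_hours <= 0) abort("`monitoring_hours` must be > 0.")
  structure(
    list(n_patients = as.integer(n_patients), af_prevalence = af_prevalence,
         known_af_fraction = known_af_fraction,
         monitoring_hours = monitoring_hours, dropout = dropout,
         effect_sizes = effect_sizes, base = base,
         sampling_rate = sampling_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate one synthetic stroke-unit patient
#'
#' Draws a latent phenotype conditioned on the AF label, generates the sinus
#' beat stream, splices short atrial runs and ectopic beats, adds AF episodes
#' (labelled patients only; their spans become the alarm interval set),
#' removes monitoring dropouts and samples clinical covariates. The latent
#' generating parameters are retained in `truth` for parameter-recovery tests.
#'
#' @param config a [cohort_config()].
#' @param patient_id patient identifier.
#' @param label `"no_af"`, `"ndaf"` or `"known_af"`.
#' @return list with `patient_id`, `label`, `beats` ([beat_stream()]),
#'   `af` (alarm intervals), `clinical` (one-row tibble), `truth` (latent
#'   parameters).
#' @export
simulate_patient <- function(config, patient_id, label = "no_af") {
  label <- match.arg(label, c("no_af", "ndaf", "known_af"))
  afp <- label != "no_af"
  b <- config$base
  ef <- config$effect_sizes
  seed_p <- derive_seed(config$seed, patient_id)
  pheno <- with_local_seed(derive_seed(seed_p, "phenotype"), {
    amp_jit <- rlnorm(1, 0, b$pheno_sdlog)
    start_sec <- runif(1, 0, 86400)
    list(
      mean_rr = clip_num(rnorm(1, b$mean_rr, b$mean_rr_sd), 550, 1300),
      lf_amp = b$lf_amp * amp_jit,
      hf_amp = b$hf_amp * amp_jit * (if (afp) ef$rmssd_ratio else 1),
      noise_amp = b$noise_amp * amp_jit * (if (afp) ef$rmssd_ratio else 1),
      noise_beta = b$noise_beta + (if (afp) 2 * ef$dfa_alpha1_shift else 0),
      sves_rate = b$sves_rate * (if (afp) ef$sves_rate_ratio else 1),
      ves_rate = b$ves_rate,
      short_run_rate = if (afp) ef$short_run_rate else b$short_run_rate,
      recording_start = as.POSIXct("2022-03-01 00:00:00", tz = "UTC") + start_sec
    )
  })
  prof <- rr_profile(mean_rr = pheno$mean_rr, lf_amp = pheno$lf_amp,
                     hf_amp = pheno$hf_amp, noise_amp = pheno$noise_amp,
                     noise_beta = pheno$noise_beta)
  bs <- simulate_rr_series(prof, config$monitoring_hours, seed = seed_p,
                           recording_start = pheno$recording_start,
                           patient_id = patient_id)
  bs <- inject_short_runs(bs, pheno$short_run_rate, seed = seed_p)
  bs <- inject_ectopy(bs, pheno$sves_rate, pheno$ves_rate, seed = seed_p)
  af <- af_intervals()
  if (afp && b$af_episode_rate > 0) {
    res <- inject_af_episodes(bs, b$af_episode_rate, b$af_episode_mean_s, seed = seed_p)
    bs <- res$stream
    af <- res$af
  }
  bs <- insert_monitoring_gaps(bs, config$dropout, seed = seed_p)
  clinical <- sample_clinical_features(label, ef, seed = seed_p)
  list(patient_id = patient_id, label = label, beats = bs, af = af,
       clinical = clinical, truth = pheno)
}

#' Simulate a synthetic stroke-unit monitoring cohort
#'
#' Generates `n_patients` independent patients. Labels are Bernoulli draws:
#' `known_af` with probability `known_af_fraction`, otherwise `ndaf` with
#' probability `af_prevalence`. Patients with `label == "no_af"` never carry
#' AF alarm intervals.
#'
#' @param config a [cohort_config()].
#' @return tibble with one row per patient: `patient_id`, `label`,
#'   unnested clinical covariate columns, and list-columns `beats`, `af`,
#'   `truth`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(n_patients = 4, monitoring_hours = 0.5))
#' coh$label
#' }
#' @export
simulate_cohort <- function(config) {
  ids <- sprintf("p%04d", seq_len(config$n_patients))
  labels <- with_local_seed(derive_seed(config$seed, "labels"), {
    u <- runif(config$n_patients)
    v <- runif(config$n_patients)
    ifelse(u < config$known_af_fraction, "known_af",
           ifelse(v < config$af_prevalence, "ndaf", "no_af"))
  })
  pats <- map2(ids, labels, function(id, lab) simulate_patient(config, id, lab))
  tibble(
    patient_id = ids,
    label = labels,
    purrr::list_rbind(map(pats, "clinical")),
    beats = map(pats, "beats"),
    af = map(pats, "af"),
    truth = map(pats, "truth")
  )
}

#' Write a cohort to plain-text files
#'
#' One beat CSV (`<id>_beats.csv`: `time_s,label`) and one alarm CSV
#' (`<id>_alarms.csv`: `start_s,end_s`) per patient, a cohort-level
#' `clinical.csv` (one row per patient, including the AF label) and a JSON
#' manifest with the generating configuration summary.
#'
#' @param cohort tibble from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$patient_id[i]
    bs <- cohort$beats[[i]]
    utils::write.csv(tibble(time_s = bs$time_s, label = bs$label),
                     file.path(dir, paste0(id, "_beats.csv")), row.names = FALSE)
    utils::write.csv(cohort$af[[i]],
                     file.path(dir, paste0(id, "_alarms.csv")), row.names = FALSE)
  }
  clin <- select(cohort, -any_of(c("beats", "af", "truth")))
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  manifest <- list(
    n_patients = nrow(cohort),
    labels = as.list(table(cohort$label)),
    files = list(beats = paste0(cohort$patient_id, "_beats.csv"),
                 alarms = paste0(cohort$patient_id, "_alarms.csv"),
                 clinical = "clinical.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a beat CSV written by [write_cohort()]
#' @param path CSV file with columns `time_s`, `label`
#' @param ... passed to [beat_stream()] (patient_id, recording_start, ...)
#' @return a [beat_stream()]
#' @export
read_beat_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  beat_stream(df$time_s, df$label, ...)
}

#' Read an alarm CSV written by [write_cohort()]
#' @param path CSV file with columns `start_s`, `end_s`
#' @return an [af_intervals()] tibble
#' @export
read_alarm_csv <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) return(af_intervals())
  af_intervals(df$start_s, df$end_s)
}
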