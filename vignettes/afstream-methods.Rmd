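---
title: "Predicting atrial fibrillation after stroke from monitoring beat streams: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting atrial fibrillation after stroke from monitoring beat streams: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(afstream)
```

## The clinical problem

Paroxysmal atrial fibrillation (AF) causes a large fraction of ischaemic
strokes but is easy to miss: episodes may be brief, asymptomatic, and absent
during routine work-up. Stroke units monitor patients continuously for the
first days after admission, producing long streams of automatically labelled
heartbeats (normal `N`, supraventricular extrasystole `S`, ventricular
extrasystole `V`, other/artefact `O`), AF alarm intervals from the monitor's
own detector, and a routine clinical data set. The question this package
addresses is risk stratification: given the *sinus-rhythm* part of a
patient's monitoring (all detected AF removed) and basic clinical data, how
likely is this patient to have AF detected during the stay? A well-calibrated
ranking lets a unit concentrate prolonged cardiac monitoring on the patients
most likely to benefit.

The package implements the full derivation–validation machinery around a
simple final model — a tree-based ensemble over the patient's age and 19
heart-rate-variability (HRV) features computed from the first hour of
monitoring — together with the richer comparison models it was distilled
from (clinical-only ensembles, HRV ensembles, a small 1-D convolutional
network on raw ECG segments, and a Bayesian fusion of both), and the
statistical layer used to compare them.

## The processing model, stage by stage

**Eligibility.** A record qualifies for analysis when at least 3 h of
effective monitoring fall inside the core daytime window (09:00–18:00) *and*
at least 3 h inside the core nighttime window (21:00–06:00), accumulated over
the whole record (`check_monitoring_coverage()`). We read the requirement as
a total over the record rather than per 24-h period; with 72-h records the
two readings rarely differ, and the total is the weaker, more inclusive rule.

**AF removal.** Alarm intervals are excised with a 2.5-min buffer on each
side (`excise_af_intervals()`), so that the analysed stream is AF-free sinus
rhythm with a margin around each detected episode. Intervals are half-open
`[start, end)` in seconds from recording start throughout the package; the
buffer windows are merged where they overlap and clipped at the record
boundaries.

**Beat cleaning.** Beats labelled `O` are removed entirely
(`clean_beats()`); the RR interval across a removal point is treated as
undefined rather than bridged. Gaps shorter than 3 s are then filled by
local-RR interpolation (`interpolate_short_gaps()`): `round(gap / local
median RR) - 1` beats, evenly spaced. Bedside monitoring pipelines usually
delegate this to vendor peak-correction routines whose internals are not
specified; the even-spacing rule is deliberately simple so that it can serve
as its own test oracle. Gaps of 3 s or longer become segment boundaries.

**Segmentation.** RR data between boundaries are concatenated (gap time
excluded) and tiled greedily into 5-min segments (`segment_rr_5min()`); a
residual shorter than 5 min is discarded. Concatenating *before* tiling
means a 4-min run, a long gap and another 4-min run still produce one valid
segment — the interpretation that minimises data loss. Each segment is
tagged with the hour (since recording start) of its first beat; recording
start is the admission proxy.

**Raw ECG.** For the convolutional model, the 500-Hz lead-II trace is tiled
into non-overlapping 5.12-s windows (2560 samples), each band-pass filtered
with a zero-phase order-4 Butterworth (0.5–50 Hz). Windows with fewer than
three beats or any beat outside `{N, S, V}` are invalid; 80 valid windows
per patient are sampled with a fixed seed (`segment_raw_ecg()`).

## The 19-feature HRV bank

Per 5-min segment, `hrv_features()` computes six time-domain statistics
(`mean_rr`, `median_rr`, `sdnn`, `cvnn`, `rmssd`, `pnn50`), four spectral
powers from a 4-Hz cubic-spline-resampled tachogram under Welch's method
(`tp` 0.003–0.4 Hz, `lf` 0.04–0.15 Hz, `hf` 0.15–0.4 Hz, `lf_hf`), five
nonlinear measures (DFA exponents `dfa_alpha1` over scales 4–16 and
`dfa_alpha2` over 16–64; sample entropy with `m = 2`, `r = 0.2·SD`;
multiscale entropy averaged over coarse-graining scales 1–5; the Poincaré
descriptors `sd1`, `sd2`, `sd1_sd2`), and two ectopy ratios (`s2n`, `v2n`:
extrasystoles per normal beat). Nine of these (TP, HF, LF, RMSSD, DFA,
pNN50, MSE, SDNN, S2N) form the canonical core of the bank; the remaining
ten are their standard companions, chosen once to preserve the count of 19
as the default contract. No detrending is applied before the nonlinear
features — detrending is known to distort them.

Welch parameters (4 Hz resampling, 256-sample Hann windows, 50 % overlap)
and the DFA/MSE scale ranges are standard HRV practice; they are exposed as
arguments but the defaults are fixed and tested. Per-feature hourly means
over valid segments, then the mean over hours in the analysis window, give
one row per patient (`hourly_aggregate()`); the final model restricts to
segments starting in the first hour (`restrict_first_hours()`).

Missing features (too few beats, zero HF power, constant series) carry an
explicit reason and are median-imputed *inside each training fold* at model
time, never globally.

## Models and validation protocol

All models share one patient-level stratified shuffle-split plan
(`make_patient_splits()`: 5 splits, 20 % test fraction, one seed), so that
per-fold comparisons are paired. The ensemble layer (`train_ensemble()`)
is a documented randomized search over three families — penalized logistic regression, random forest,
gradient boosting — scored by ROC-AUC under an inner 3-fold stratified CV on
the training fold only (the inner k is unstated in the protocol we follow;
3 is the smallest value that keeps every inner fold two-class at 6 %
prevalence). Class imbalance is handled by stratification plus inverse-class
weights. The searcher, not any single family, is the contract — a transparent stand-in for opaque AutoML ensembling.

The convolutional model (`train_cnn()`) is a deliberately small stand-in for
the large raw-ECG networks of the literature, whose exact topologies are
not public: one
1-D convolution (8 filters, 128-sample kernel ≈ 256 ms, stride 16), ReLU,
global average *and* max pooling, sigmoid output, trained with Adam at
learning rate 0.001 for 20 epochs under binary cross-entropy. The 256-ms
kernel spans a full P-QRS complex, which is what allows the network to react
to absent P waves and irregular R-R spacing; max pooling makes localized
morphology visible through the global pool. Per-patient scores average `k`
sampled segment probabilities (`aggregate_segment_predictions()`), mirroring
the performance-versus-segment-count analysis.

Fusion (`bayes_fuse()`) combines two models' probabilities by the
independent-odds product `p1·p2 / (p1·p2 + (1-p1)(1-p2))` — the posterior
under conditionally independent evidence with prior 0.5, i.e. adding
log-odds. The pair (0, 1) is singular, so inputs are clipped to
`[1e-6, 1 - 1e-6]`; the clip is far below any probability resolution the
models produce. The AS5F benchmark (`as5f_score()`) takes its coefficients
as injected configuration: the published coefficients belong to the original
AS5F publication and are deliberately not shipped; a generic monotone
surrogate (`illustrative_as5f_coefficients()`) exercises the benchmarking
code on synthetic cohorts.

Evaluation (`evaluate_predictions()`, `delong_test()`, `fisher_combine()`,
`threshold_at_specificity()`, `paired_bootstrap_metric_test()`) follows the
protocol: mean ROC-AUC over folds, percentile bootstrap CIs (stratified
patient resampling; 200 resamples per derivation fold, 1000 for validation),
fold-wise paired DeLong tests aggregated by Fisher's method, a decision
threshold frozen at 90 % specificity on derivation data, and paired
bootstrap t-tests for sensitivity/PPV/NPV differences. The threshold is
anchored on *cross-fitted* derivation scores of the deployed model's own
configuration (`cross_fitted_scores()`), not on pooled outer-CV scores:
the five outer-fold models are independently searched and may come from
different families with incompatible probability scales, so a quantile of
their pooled scores does not correspond to any quantile of the deployed
model's scores — anchoring on same-configuration cross-fitted scores is
what makes the frozen threshold transfer. Percentile (not BCa)
intervals are used — nothing in the protocol demands more, and percentile
intervals are exactly reproducible at small resample counts. Degenerate
DeLong comparisons (zero variance of the AUC difference) return p = 1 by
convention.

## The synthetic cohort generator

Real stroke-unit monitoring data cannot be shared, so the package carries a
first-class generator (`simulate_cohort()`) whose defaults *are* the study
conditions of every test in this package:

* **Sinus rhythm** by an integral-pulse-frequency-modulation model: base RR
  ~ N(850, 70) ms across patients, LF (0.1 Hz) and HF (0.25 Hz) sinusoidal
  modulation of 25 and 20 ms, plus `1/f^beta` noise of 20 ms with
  `beta = 1`. This gives controllable ground truth for spectral and
  scaling features: DFA of `1/f^beta` noise has exponent ≈ `(beta + 1)/2`.
* **AF-prone phenotype**: HF and broadband amplitudes scaled by
  `rmssd_ratio = 1.5`; `beta` shifted by `2 × dfa_alpha1_shift = -0.3`
  (targeting a DFA-α1 reduction of 0.15); supraventricular ectopy 15/h
  versus 5/h (`sves_rate_ratio = 3`); short atrial runs (5–20 s,
  below the 30-s AF definition, invisible to the alarm set) at 2/h versus
  0.1/h; age shifted by +8.3 years — the direction and rough magnitude of
  group contrasts reported for stroke-unit cohorts (mean age about 79 vs 71). The
  paper states no quantitative HRV effect sizes, so these are configuration,
  chosen once to represent a clearly AF-prone phenotype, not paper facts.
* **AF episodes** in labelled patients (1/h, 30 s + Exp(60 s)): RR drawn
  i.i.d. from a broad lognormal — serial independence is the defining,
  testable property of AF irregularity here; no atrial electrophysiology is
  modelled. Episode spans become the alarm intervals that preprocessing
  must excise.
* **Monitoring dropouts** at 0.15/h with ~10-min mean length; day/night
  structure through a random wall-clock recording start.
* **Clinical covariates** from parametric distributions matching the group
  contrasts reported for stroke-unit cohorts in direction and rough
  magnitude; prevalence of newly detected AF defaults to 6 %.
* **Raw ECG** (`synthesize_ecg()`) as Gaussian-bump P-QRS-T templates at
  each beat time, with P waves omitted and a fibrillatory 6.5-Hz baseline
  inside AF episodes and short runs.

One RNG stream per patient is derived from `(seed, patient_id)`, so cohorts
are byte-reproducible regardless of generation order.

What the generator does *not* emulate — circadian autonomic trends,
medication effects, lead noise and artefact bursts, realistic 12-lead
morphology, imperfect alarm labels — bounds what passing tests can show:
they demonstrate that the pipeline recovers planted structure under its own
assumptions, not that clinically reported performance figures transfer.
Reported clinical performances of such models (ROC-AUCs of 0.88–0.89 on
derivation data, ≈ 0.79 on external validation against ≈ 0.69 for AS5F)
are properties of non-public patient cohorts and are out of reach by
design.

## Problem sizes used by the tests and the acceptance script

The shipped checks run on desk-scale cohorts chosen once: the end-to-end
recovery and threshold-transfer experiments use 400 patients at 6 %
prevalence monitored for 2 h (the final model consumes only hour 0; the
spec-level default of 72 h remains available through `monitoring_hours`);
null calibration permutes the labels of that cohort 50 times; the CNN
sub-study uses 40 patients at 50 % prevalence with 20-min records and an
enriched short-run rate (30/h) so that enough arrhythmic windows exist in
records that short — it is a qualitative check of the
aggregation-versus-k behaviour, not a power study.

## Numerical and degenerate-input conventions

* Constant RR series: `sampen = 0` (all templates match), DFA undefined,
  spectral power ~0. Zero HF power makes `lf_hf` missing with a reason.
* `sd2` is `sqrt(2·sdnn² - sd1²)`, missing when the radicand is negative.
* Specificity thresholds are score values (predicted positive = `score ≥
  threshold`), the smallest candidate meeting the target; ties resolve in
  favour of sensitivity automatically.
* Fisher combination clips p = 0 to the smallest positive double with a
  warning.
* All stochastic steps take an explicit seed and restore the caller's RNG
  state; derived seeds stay below 2^31.

## Known limitations

The ensemble search space is compact (three families, six candidates by
default) — adequate for the planted-effect cohorts, smaller than a
production AutoML run. The CNN is a capacity-limited stand-in; its role here
is to demonstrate the protocol (weak labels, patient-level splits, k-segment
aggregation), not to match a large network's raw-ECG performance. Kernel
SHAP attributions use the training-median reference, the common but
reference-dependent choice. The gap-interpolation rule is a simple contract,
not a reimplementation of any published correction routine.
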