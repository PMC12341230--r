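#' Bayesian odds-product fusion of two classifier probabilities
#'
#' Combines two AF probabilities for the same patient by
#' `p1 * p2 / (p1 * p2 + (1 - p1) * (1 - p2))` — the posterior under two
#' conditionally independent evidence sources with prior 0.5, equivalent to
#' adding the two log-odds. The formula is symmetric in its arguments,
#' strictly increasing in each on (0, 1), and has 0.5 as the identity
#' element. The degenerate pair (0, 1) is undefined (0/0), so inputs are
#' clipped to `[eps, 1 - eps]` first.
#'
#' @param p1,p2 probabilities in `[0, 1]` (vectorized).
#' @param eps clipping bound (default 1e-6).
#' @return fused probabilities.
#' @examples
#' bayes_fuse(0.8, 0.6)  # 0.48 / (0.48 + 0.08) = 0.857...
#' bayes_fuse(0.7, 0.5)  # 0.5 is neutral evidence: returns 0.7
#' @export
bayes_fuse <- function(p1, p2, eps = 1e-6) {
  if (any(!is.finite(p1)) || any(!is.finite(p2))) {
    abort("Fusion inputs must be finite probabilities.")
  }
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    abort("Fusion inputs must lie in [0, 1].")
  }
  p1 <- pmin(pmax(p1, eps), 1 - eps)
  p2 <- pmin(pmax(p2, eps), 1 - eps)
  num <- p1 * p2
  num / (num + (1 - p1) * (1 - p2))
}

#' Fuse two prediction sets patient-by-patient
#'
#' @param preds_a,preds_b tibbles with `patient_id` and `prob`, covering the
#'   same patients.
#' @param eps clipping bound passed to [bayes_fuse()].
#' @return tibble `patient_id`, `prob` (fused), plus any `label`/`fold`
#'   columns carried over from `preds_a`.
#' @export
fuse_predictions <- function(preds_a, preds_b, eps = 1e-6) {
  if (!setequal(preds_a$patient_id, preds_b$patient_id)) {
    abort("Prediction sets cover different patients; fusion requires pairing.")
  }
  b <- preds_b$prob[match(preds_a$patient_id, preds_b$patient_id)]
  mutate(preds_a, prob = bayes_fuse(.data$prob, b, eps = eps))
}

#' AS5F-style clinical benchmark score from age and NIHSS
#'
#' A deterministic ranking score over age and admission NIHSS, the two inputs
#' of the published AS5F score. The published coefficients are *not* shipped
#' with this package: they must be supplied from the original AS5F
#' publication via `coefficients` (a named list with `age`, `nihss` and
#' optionally `nihss_gt5` and `intercept` entries; all slope terms must be
#' non-negative so the score is monotone in both inputs). For synthetic
#' benchmarking, [illustrative_as5f_coefficients()] provides a generic
#' monotone surrogate.
#'
#' @param clinical tibble with `age` and `nihss` columns.
#' @param coefficients named list of coefficients (see above).
#' @return numeric score vector (a ranking score, not a probability).
#' @export
as5f_score <- function(clinical, coefficients = NULL) {
  if (is.null(coefficients)) {
    abort(paste("AS5F coefficients must be supplied from the original AS5F",
                "publication (or use illustrative_as5f_coefficients() for",
                "synthetic benchmarking)."))
  }
  co <- modifyList(list(intercept = 0, age = 0, nihss = 0, nihss_gt5 = 0),
                   coefficients)
  if (co$age < 0 || co$nihss < 0 || co$nihss_gt5 < 0) {
    abort("AS5F slope coefficients must be non-negative (monotone score).")
  }
  stopifnot(all(clinical$age > 0), all(clinical$nihss >= 0 & clinical$nihss <= 42))
  co$intercept + co$age * clinical$age + co$nihss * clinical$nihss +
    co$nihss_gt5 * (clinical$nihss > 5)
}

#' Illustrative monotone coefficients for the AS5F-style benchmark
#'
#' A generic surrogate used to exercise the benchmarking code on synthetic
#' cohorts. These are *not* the published AS5F coefficients; analyses of real
#' data must inject the coefficients from the original publication.
#'
#' @return named list with `age` and `nihss_gt5` entries.
#' @export
illustrative_as5f_coefficients <- function() {
  list(age = 1, nihss_gt5 = 10)
}
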