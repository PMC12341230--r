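#' Patient-level stratified shuffle-split plan
#'
#' Builds the cross-validation plan used by every model in a comparison run:
#' `n_splits` independent stratified shuffle splits with a `test_frac` test
#' set, sampled at the patient level so no patient contributes to both sides
#' of a fold. Reusing one plan across model kinds keeps per-fold test sets
#' identical, which is what makes fold-wise paired DeLong comparisons
#' well-defined.
#'
#' @param labels tibble with columns `patient_id` and `label` (0/1, logical,
#'   or a factor with the positive class second).
#' @param n_splits number of shuffle splits (default 5).
#' @param test_frac test-set fraction (default 0.2).
#' @param seed integer seed.
#' @return a `split_plan` tibble: `fold`, list-columns `train`, `test` of
#'   patient ids.
#' @examples
#' labs <- tibble::tibble(patient_id = sprintf("p%02d", 1:20),
#'                        label = rep(c(0, 1), c(16, 4)))
#' plan <- make_patient_splits(labs, seed = 7)
#' lengths(plan$test)  # 4 patients per test set, stratified
#' @export
make_patient_splits <- function(labels, n_splits = 5, test_frac = 0.2, seed = 1) {
  y <- as.integer(as.logical_label(labels$label))
  pos <- labels$patient_id[y == 1]
  neg <- labels$patient_id[y == 0]
  if (length(pos) < 2 || length(neg) < 2) {
    abort("Each class needs at least 2 patients for stratified splitting.")
  }
  n_test_pos <- max(1L, round(length(pos) * test_frac))
  n_test_neg <- max(1L, round(length(neg) * test_frac))
  with_local_seed(derive_seed(seed, "splits"), {
    folds <- map(seq_len(n_splits), function(f) {
      tp <- sample(pos, n_test_pos)
      tn <- sample(neg, n_test_neg)
      test <- c(tp, tn)
      tibble(fold = f,
             train = list(setdiff(labels$patient_id, test)),
             test = list(test))
    })
    out <- list_rbind(folds)
    structure(out, seed = seed, test_frac = test_frac,
              class = c("split_plan", class(out)))
  })
}

# coerce a label vector to logical (positive class = 1 / TRUE / last level)
as.logical_label <- function(x) {
  if (is.logical(x)) return(x)
  if (is.factor(x)) return(x == levels(x)[length(levels(x))])
  if (is.character(x)) return(x %in% c("1", "TRUE", "ndaf", "known_af", "af", "yes"))
  x != 0
}
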