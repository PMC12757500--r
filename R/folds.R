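# Cross-validation folds and class-imbalance oversampling.

#' Stratified cross-validation fold assignment
#'
#' Partitions patients into `k` folds stratified jointly on (outcome x
#' race), so every fold carries a comparable race composition and event
#' rate. Within each stratum, patients are shuffled under the seed and
#' dealt round-robin; deterministic given `seed`.
#'
#' @param outcome Logical/0-1 outcome vector.
#' @param race Race labels, same length.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer vector of fold indices in `1:k`.
#' @export
make_cv_folds <- function(outcome, race, k = 5, seed = 42) {
  if (k < 2) stop("k must be >= 2")
  if (length(outcome) != length(race)) stop("outcome and race lengths differ")
  strata <- interaction(as.integer(outcome), race, drop = TRUE)
  if (any(table(strata) < k)) {
    small <- names(which(table(strata) < k))
    stop("stratum smaller than k folds: ", paste(small, collapse = ", "))
  }
  folds <- integer(length(outcome))
  with_seed_(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Expand training indices by duplicating minority-class examples
#'
#' Returns the training indices with every minority-class index repeated
#' `factor` times in total (original order preserved, duplicates appended
#' in order). Applied only to the fitting portion of a training fold,
#' never to validation or test rows.
#'
#' @param indices Integer row indices of the fitting portion.
#' @param labels Binary labels aligned with `indices`.
#' @param factor Integer duplication factor >= 1; 1 is the identity.
#' @return Expanded integer index vector.
#' @export
oversample_duplicate <- function(indices, labels, factor = 2) {
  if (length(indices) != length(labels)) stop("indices and labels lengths differ")
  if (factor < 1 || factor != round(factor)) stop("factor must be an integer >= 1")
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary")
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (any(tab == 0)) stop("both classes must be present to oversample")
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  extra <- rep(indices[y == minority], factor - 1)
  c(indices, extra)
}
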