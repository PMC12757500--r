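# Decision-curve analysis: net benefit of model-guided intervention
# against the treat-all and treat-none reference strategies.

#' Net benefit of intervening on flagged patients
#'
#' `TP/N - (FP/N) * p_t / (1 - p_t)`: the per-patient rate of true-positive
#' interventions after discounting false positives at the odds of the risk
#' threshold. May be negative.
#'
#' @param counts A `ckd_confusion` at threshold `p_t`.
#' @param p_t Risk threshold in (0, 1); defaults to the counts' threshold.
#' @return Net benefit in true-positive equivalents per patient.
#' @export
net_benefit <- function(counts, p_t = counts$threshold) {
  stopifnot(inherits(counts, "ckd_confusion"))
  if (is.na(p_t) || p_t <= 0 || p_t >= 1) {
    stop("p_t must lie strictly in (0, 1)")
  }
  counts$tp / counts$n - (counts$fp / counts$n) * p_t / (1 - p_t)
}

#' Net benefit of the treat-all and treat-none reference strategies
#'
#' Treat-all: `prevalence - (1 - prevalence) * p_t / (1 - p_t)` (zero
#' exactly at `p_t` = prevalence); treat-none: 0 at every threshold.
#'
#' @param prevalence Event prevalence in (0, 1).
#' @param p_t Risk threshold in (0, 1).
#' @return List with `treat_all` and `treat_none`.
#' @export
reference_strategies <- function(prevalence, p_t) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  if (any(p_t <= 0 | p_t >= 1)) stop("p_t must lie strictly in (0, 1)")
  list(treat_all = prevalence - (1 - prevalence) * p_t / (1 - p_t),
       treat_none = 0)
}

#' Decision curve over a threshold grid
#'
#' Net benefit of model-guided intervention (flagging at `score >= p_t`)
#' across thresholds, with the treat-all and treat-none references.
#' Intended for out-of-fold predictions only.
#'
#' @inheritParams auc
#' @param grid Thresholds (default 5% to 50% in 1-point steps).
#' @return Data frame with `threshold`, `nb_model`, `nb_treat_all`,
#'   `nb_treat_none`.
#' @export
decision_curve <- function(scores, labels, grid = seq(0.05, 0.50, by = 0.01)) {
  if (length(grid) == 0) stop("threshold grid must be non-empty")
  prev <- mean(as.numeric(labels))
  rows <- lapply(grid, function(p_t) {
    nb <- net_benefit(confusion_at_threshold(scores, labels, p_t), p_t)
    ref <- reference_strategies(prev, p_t)
    data.frame(threshold = p_t, nb_model = nb,
               nb_treat_all = ref$treat_all, nb_treat_none = ref$treat_none)
  })
  do.call(rbind, rows)
}
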