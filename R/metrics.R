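# Discrimination, calibration and group-fairness metrics, computed from
# out-of-fold predictions per race and overall.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUC with ties counted one half; equals the proportion of
#' positive-negative pairs ranked concordantly.
#'
#' @param scores Predicted risks.
#' @param labels Binary outcomes; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  r <- rank(scores)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong structural components via midranks: V10 for positives, V01 for
# negatives
delong_components_ <- function(scores, labels) {
  y <- as.integer(labels)
  x_pos <- scores[y == 1]
  x_neg <- scores[y == 0]
  m <- length(x_pos); n <- length(x_neg)
  all_r <- rank(c(x_pos, x_neg))
  r_pos <- rank(x_pos)
  r_neg <- rank(x_neg)
  v10 <- (all_r[seq_len(m)] - r_pos) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - r_neg) / m
  a <- (sum(all_r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = a, var = stats::var(v10) / m + stats::var(v01) / n)
}

#' DeLong test for an AUC difference between two independent groups
#'
#' Estimates each group's AUC variance with the DeLong structural
#' components and tests the difference with an independent two-sample
#' z-test (the groups are disjoint patient sets).
#'
#' @param scores_1,labels_1 Scores and outcomes of group 1.
#' @param scores_2,labels_2 Scores and outcomes of group 2.
#' @return List with `auc1`, `auc2`, `diff` (group 1 - group 2), variances,
#'   `z` and two-sided `p`.
#' @export
delong_auc_difference <- function(scores_1, labels_1, scores_2, labels_2) {
  if (length(unique(as.integer(labels_1))) < 2 ||
      length(unique(as.integer(labels_2))) < 2) {
    stop("each group must contain both outcome classes")
  }
  c1 <- delong_components_(scores_1, labels_1)
  c2 <- delong_components_(scores_2, labels_2)
  d <- c1$auc - c2$auc
  se <- sqrt(c1$var + c2$var)
  z <- if (se == 0) 0 else d / se
  list(auc1 = c1$auc, auc2 = c2$auc, diff = d,
       var1 = c1$var, var2 = c2$var,
       z = z, p = 2 * pnorm(-abs(z)))
}

#' Brier score
#'
#' Mean squared error of predicted probabilities.
#'
#' @inheritParams auc
#' @return Brier score in [0, 1].
#' @export
brier <- function(scores, labels) {
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  mean((scores - as.numeric(labels))^2)
}

#' Equal-frequency reliability bins
#'
#' Sorts predictions into `n_bins` equal-frequency groups (ties broken by
#' a stable sort on score then id) and reports each bin's size, mean
#' predicted risk and observed event rate. Bin counts differ by at most
#' one, with the larger bins first.
#'
#' @inheritParams auc
#' @param n_bins Number of bins (default 10, i.e. risk deciles).
#' @param ids Tie-break identifiers (default input order).
#' @return Data frame with columns `bin`, `n`, `mean_pred`, `obs_rate`.
#' @export
reliability_bins <- function(scores, labels, n_bins = 10,
                             ids = seq_along(scores)) {
  n <- length(scores)
  if (n < n_bins) stop("need at least n_bins observations")
  ord <- order(scores, ids)
  sizes <- rep(floor(n / n_bins), n_bins)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin <- rep(seq_len(n_bins), times = sizes)
  s <- scores[ord]; y <- as.numeric(labels)[ord]
  data.frame(
    bin = seq_len(n_bins),
    n = sizes,
    mean_pred = as.vector(tapply(s, bin, mean)),
    obs_rate = as.vector(tapply(y, bin, mean))
  )
}

#' Expected calibration error from reliability bins
#'
#' Frequency-weighted mean absolute gap between bin-wise predicted and
#' observed rates; zero iff every bin lies on the diagonal.
#'
#' @param bins Output of [reliability_bins()].
#' @return ECE (>= 0).
#' @export
ece <- function(bins) {
  if (is.null(bins) || nrow(bins) == 0) stop("bins must be non-empty")
  sum(bins$n / sum(bins$n) * abs(bins$obs_rate - bins$mean_pred))
}

#' Calibration-in-the-large
#'
#' `100 * (mean(scores) - mean(labels))` in percentage points; negative
#' values indicate systematic under-prediction.
#'
#' @inheritParams auc
#' @return Difference in percentage points.
#' @export
calibration_in_the_large <- function(scores, labels) {
  if (length(scores) == 0) stop("scores must be non-empty")
  100 * (mean(scores) - mean(as.numeric(labels)))
}

#' Calibration slope via logistic recalibration
#'
#' Fits `outcome ~ logit(score)` by maximum-likelihood logistic regression
#' (IWLS, convergence tolerance 1e-8) and returns the slope with a 95%
#' Wald interval from the observed information. A slope of 1 is ideal;
#' < 1 indicates overfitted (too extreme) predictions.
#'
#' @param scores Predicted risks strictly inside (0, 1), non-constant.
#' @param labels Binary outcomes, both classes present.
#' @return List with `slope`, `se`, `ci` (length-2), `intercept`.
#' @export
calibration_slope <- function(scores, labels) {
  if (any(scores <= 0 | scores >= 1)) stop("scores must lie strictly in (0, 1)")
  if (sd(scores) == 0) stop("slope unidentifiable: scores are constant")
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  lp <- qlogis(scores)
  fit <- glm(y ~ lp, family = binomial(),
             control = glm.control(epsilon = 1e-8, maxit = 100))
  est <- coef(fit)[["lp"]]
  se <- sqrt(vcov(fit)["lp", "lp"])
  list(slope = est, se = se,
       ci = est + c(-1, 1) * qnorm(0.975) * se,
       intercept = coef(fit)[["(Intercept)"]])
}

#' Confusion counts at a risk threshold
#'
#' Flags a patient as high-risk when `score >= p_t` (boundary inclusive,
#' the convention used throughout, including decision-curve analysis).
#'
#' @inheritParams auc
#' @param p_t Risk threshold in (0, 1).
#' @param group Optional group label carried along.
#' @return Object of class `ckd_confusion` with `tp`, `fp`, `tn`, `fn`,
#'   `n`, `threshold`, `group`.
#' @export
confusion_at_threshold <- function(scores, labels, p_t, group = NA_character_) {
  if (p_t <= 0 || p_t >= 1) stop("p_t must lie strictly in (0, 1)")
  y <- as.integer(labels)
  flag <- scores >= p_t
  confusion_counts(tp = sum(flag & y == 1), fp = sum(flag & y == 0),
                   tn = sum(!flag & y == 0), fn = sum(!flag & y == 1),
                   threshold = p_t, group = group)
}

#' Construct confusion counts directly
#'
#' @param tp,fp,tn,fn Non-negative cell counts.
#' @param threshold Threshold the counts refer to.
#' @param group Optional group label.
#' @return Object of class `ckd_confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn, threshold = NA_real_,
                             group = NA_character_) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  n <- tp + fp + tn + fn
  if (n == 0) stop("total count must be positive")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 threshold = threshold, group = group),
            class = "ckd_confusion")
}

#' Classification rates from confusion counts
#'
#' TPR (sensitivity), FPR, PPV (precision) and the flag rate (fraction
#' labeled high-risk). PPV is `NA` when nobody is flagged - undefined is
#' reported explicitly, never silently as 0.
#'
#' @param counts A `ckd_confusion` object.
#' @return One-row data frame with `group`, `threshold`, `tpr`, `fpr`,
#'   `ppv`, `flag_rate` (fractions) plus the raw counts.
#' @export
classification_rates <- function(counts) {
  stopifnot(inherits(counts, "ckd_confusion"))
  pos <- counts$tp + counts$fn
  neg <- counts$fp + counts$tn
  flagged <- counts$tp + counts$fp
  data.frame(
    group = counts$group, threshold = counts$threshold,
    tpr = if (pos > 0) counts$tp / pos else NA_real_,
    fpr = if (neg > 0) counts$fp / neg else NA_real_,
    ppv = if (flagged > 0) counts$tp / flagged else NA_real_,
    flag_rate = flagged / counts$n,
    tp = counts$tp, fp = counts$fp, tn = counts$tn, fn = counts$fn,
    n = counts$n, stringsAsFactors = FALSE
  )
}

#' Black-White fairness gaps at a common threshold
#'
#' Elementwise Black minus White differences (percentage points) in the
#' flag rate (statistical parity), TPR and FPR (equalized odds) and PPV
#' (predictive parity), plus the per-group AUC difference when AUCs are
#' supplied. Gaps involving an undefined PPV propagate as `NA`.
#'
#' @param metrics_black,metrics_white One-row outputs of
#'   [classification_rates()] at the same threshold.
#' @param auc_black,auc_white Optional per-group AUCs.
#' @return List of gaps (`tpr_gap`, `fpr_gap`, `ppv_gap`, `flag_rate_gap`
#'   in pp; `auc_gap` on the AUC scale).
#' @export
fairness_gaps <- function(metrics_black, metrics_white,
                          auc_black = NULL, auc_white = NULL) {
  if (!isTRUE(all.equal(metrics_black$threshold, metrics_white$threshold))) {
    stop("metrics were computed at different thresholds")
  }
  list(
    threshold = metrics_black$threshold,
    tpr_gap = 100 * (metrics_black$tpr - metrics_white$tpr),
    fpr_gap = 100 * (metrics_black$fpr - metrics_white$fpr),
    ppv_gap = 100 * (metrics_black$ppv - metrics_white$ppv),
    flag_rate_gap = 100 * (metrics_black$flag_rate - metrics_white$flag_rate),
    auc_gap = if (is.null(auc_black) || is.null(auc_white)) NA_real_
              else auc_black - auc_white
  )
}

#' Pearson chi-square test for a difference in two proportions
#'
#' 2x2 Pearson chi-square without continuity correction (df = 1), applied
#' to (events, non-events) counts of two groups.
#'
#' @param counts_a,counts_b Length-2 vectors `c(events, non_events)`.
#' @return List with `statistic` and `p`.
#' @export
chi2_2x2 <- function(counts_a, counts_b) {
  m <- rbind(counts_a, counts_b)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all marginal totals must be positive")
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  if (any(ht$expected <= 0)) stop("all cell expectations must be positive")
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Per-group classification metrics across a threshold grid
#'
#' Applies [confusion_at_threshold()] and [classification_rates()] to each
#' group at every threshold, and appends Black-White gaps where both
#' groups are present.
#'
#' @inheritParams auc
#' @param groups Group labels aligned with `scores`.
#' @param grid Thresholds, all strictly inside (0, 1).
#' @return List with `metrics` (long data frame: threshold x group) and
#'   `gaps` (one row per threshold, or `NULL` without both races).
#' @export
threshold_sweep <- function(scores, labels, groups,
                            grid = seq(0.05, 0.5, by = 0.05)) {
  if (length(grid) == 0) stop("threshold grid must be non-empty")
  if (any(grid <= 0 | grid >= 1)) stop("thresholds must lie strictly in (0, 1)")
  rows <- list()
  for (p_t in grid) {
    for (g in sort(unique(groups))) {
      sel <- groups == g
      rows[[length(rows) + 1]] <- classification_rates(
        confusion_at_threshold(scores[sel], labels[sel], p_t, group = g))
    }
  }
  metrics <- do.call(rbind, rows)
  gaps <- NULL
  if (all(c("Black", "White") %in% groups)) {
    gaps <- do.call(rbind, lapply(grid, function(p_t) {
      mb <- metrics[metrics$threshold == p_t & metrics$group == "Black", ]
      mw <- metrics[metrics$threshold == p_t & metrics$group == "White", ]
      as.data.frame(fairness_gaps(mb, mw))
    }))
  }
  list(metrics = metrics, gaps = gaps)
}

#' Per-fold-averaged calibration report for one group of predictions
#'
#' Computes calibration-in-the-large, ECE and the Brier score within each
#' cross-validation fold (equal-frequency bins refit per fold) and
#' averages across folds; the calibration slope and reliability bins are
#' computed once on the pooled out-of-fold predictions, where the larger
#' sample makes them stable.
#'
#' @param predictions Out-of-fold prediction rows (one strategy, one
#'   group) with columns `risk`, `outcome`, `fold`, `id`.
#' @param n_bins Bins per fold for ECE and for the pooled reliability
#'   diagram.
#' @return List with `citl_pp`, `ece`, `brier` (fold-averaged), `slope`
#'   (pooled, with CI) and `bins` (pooled reliability bins).
#' @export
calibration_report <- function(predictions, n_bins = 10) {
  folds <- sort(unique(predictions$fold))
  per_fold <- lapply(folds, function(f) {
    d <- predictions[predictions$fold == f, ]
    b <- reliability_bins(d$risk, d$outcome, n_bins = n_bins, ids = d$id)
    c(citl = calibration_in_the_large(d$risk, d$outcome),
      ece = ece(b), brier = brier(d$risk, d$outcome))
  })
  avg <- colMeans(do.call(rbind, per_fold))
  slope <- tryCatch(calibration_slope(predictions$risk, predictions$outcome),
                    error = function(e) NULL)
  list(citl_pp = unname(avg["citl"]), ece = unname(avg["ece"]),
       brier = unname(avg["brier"]), slope = slope,
       bins = reliability_bins(predictions$risk, predictions$outcome,
                               n_bins = n_bins, ids = predictions$id))
}
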