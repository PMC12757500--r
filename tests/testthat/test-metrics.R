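# brute-force all-pairs AUC oracle (ties count one half)
auc_oracle_ <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

test_that("rank-based AUC equals the all-pairs oracle", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.3, 10), c(rep(0, 5), rep(1, 5))), 0.5)
  set.seed(7)
  for (i in 1:10) {
    n <- sample(20:500, 1)
    s <- round(runif(n), 2) # coarse grid to force ties
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    expect_identical(auc(s, y), auc_oracle_(s, y))
  }
  expect_error(auc(runif(5), rep(1, 5)), "both classes")
})

test_that("DeLong difference test is symmetric and its variance is sane", {
  set.seed(11)
  s <- runif(300); y <- rbinom(300, 1, plogis(3 * s - 1.5))
  same <- delong_auc_difference(s, y, s, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  s2 <- runif(250); y2 <- rbinom(250, 1, plogis(2 * s2 - 1))
  ab <- delong_auc_difference(s, y, s2, y2)
  ba <- delong_auc_difference(s2, y2, s, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  # bootstrap oracle for the per-group AUC variance (n = 300 group)
  boots <- replicate(2000, {
    idx <- sample.int(300, replace = TRUE)
    if (length(unique(y[idx])) < 2) NA_real_ else auc(s[idx], y[idx])
  })
  v_boot <- stats::var(boots, na.rm = TRUE)
  expect_lt(abs(ab$var1 - v_boot) / v_boot, 0.15)
  expect_error(delong_auc_difference(s, rep(1, 300), s2, y2), "both outcome")
})

test_that("DeLong variance agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s <- runif(200); y <- rbinom(200, 1, plogis(2.5 * s - 1))
  ours <- ckdfair:::delong_components_(s, y)
  ref <- pROC::var(pROC::roc(y, s, quiet = TRUE), method = "delong")
  expect_equal(ours$var, ref, tolerance = 1e-10)
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.25)
  expect_equal(brier(c(0.8, 0.2), c(1, 0)), 0.04)
  expect_error(brier(c(1.2, 0.5), c(1, 0)), "lie in")
})

test_that("equal-frequency bins and ECE follow their definitions", {
  b <- reliability_bins(runif(100), rbinom(100, 1, 0.3), n_bins = 10)
  expect_equal(b$n, rep(10, 10))
  expect_equal(sum(b$n), 100)
  # ECE hand examples
  two <- data.frame(bin = 1:2, n = c(50, 50),
                    mean_pred = c(0.2, 0.6), obs_rate = c(0.3, 0.5))
  expect_equal(ece(two), 0.1)
  one <- data.frame(bin = 1, n = 30, mean_pred = 0.4, obs_rate = 0.5)
  expect_equal(ece(one), 0.1)
  diag_bins <- data.frame(bin = 1:3, n = c(10, 10, 10),
                          mean_pred = c(0.1, 0.5, 0.9),
                          obs_rate = c(0.1, 0.5, 0.9))
  expect_equal(ece(diag_bins), 0)
  expect_error(reliability_bins(runif(5), rbinom(5, 1, 0.5), n_bins = 10),
               "at least")
  expect_error(ece(NULL), "non-empty")
  # uneven case: counts differ by at most one
  b <- reliability_bins(runif(103), rbinom(103, 1, 0.3), n_bins = 10)
  expect_true(max(b$n) - min(b$n) <= 1)
})

test_that("calibration-in-the-large reproduces the printed worked values", {
  # pooled model, Black group: mean predicted 30.7% vs observed 34.5%
  scores <- rep(0.307, 1000)
  labels <- c(rep(1, 345), rep(0, 655))
  expect_equal(calibration_in_the_large(scores, labels), -3.8)
  # pooled model, White group: 21.8% predicted vs 18.3% observed
  expect_equal(calibration_in_the_large(rep(0.218, 1000),
                                        c(rep(1, 183), rep(0, 817))), 3.5)
  expect_equal(calibration_in_the_large(c(0.3, 0.7), c(0, 1)), 0)
  expect_error(calibration_in_the_large(numeric(0), numeric(0)), "non-empty")
})

test_that("the calibration slope recovers the generating logit scale", {
  set.seed(2024)
  s <- plogis(rnorm(20000, -1, 1.2))
  y <- rbinom(length(s), 1, s)
  fit <- calibration_slope(s, y)
  expect_equal(fit$slope, 1, tolerance = 0.05)
  expect_true(fit$ci[1] < 1 && 1 < fit$ci[2])
  # doubling the logits halves the slope
  s2 <- plogis(2 * qlogis(s))
  fit2 <- calibration_slope(s2, y)
  expect_equal(fit2$slope, 0.5, tolerance = 0.05)
  expect_error(calibration_slope(rep(0.3, 100), rbinom(100, 1, 0.3)),
               "constant")
})

test_that("thresholding is boundary-inclusive and counts partition", {
  cc <- confusion_at_threshold(c(0.2, 0.3, 0.35), c(0, 1, 1), 0.3)
  expect_equal(cc$tp + cc$fp, 2) # 0.3 and 0.35 flagged
  cc2 <- confusion_at_threshold(c(0.1, 0.2), c(1, 0), 0.9)
  expect_equal(cc2$tp + cc2$fp, 0)
  set.seed(5)
  s <- runif(50); y <- rbinom(50, 1, 0.4)
  cc3 <- confusion_at_threshold(s, y, 0.4)
  expect_equal(cc3$fn, sum(y) - cc3$tp)
  expect_equal(cc3$tn, sum(1 - y) - cc3$fp)
  expect_equal(cc3$n, 50)
  expect_error(confusion_at_threshold(s, y, 0), "strictly in")
})

test_that("classification rates handle undefined PPV explicitly", {
  m <- classification_rates(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 5,
                                             threshold = 0.3))
  expect_true(is.na(m$ppv))
  expect_equal(m$flag_rate, 0)
})

test_that("fairness gaps are Black minus White in percentage points", {
  mb <- classification_rates(confusion_counts(tp = 510, fp = 365, tn = 1795,
                                              fn = 330, threshold = 0.3,
                                              group = "Black"))
  mw <- classification_rates(confusion_counts(tp = 294, fp = 144, tn = 3456,
                                              fn = 606, threshold = 0.3,
                                              group = "White"))
  g <- fairness_gaps(mb, mw)
  expect_equal(g$tpr_gap, 100 * (510 / 840 - 294 / 900))
  expect_equal(round(g$fpr_gap, 1), 12.9)
  same <- fairness_gaps(mb, mb)
  expect_equal(same$tpr_gap, 0)
  expect_equal(same$flag_rate_gap, 0)
  mw2 <- mw; mw2$threshold <- 0.2
  expect_error(fairness_gaps(mb, mw2), "different thresholds")
})

test_that("the 2x2 chi-square matches hand-computed Pearson cells", {
  # independent oracle: Pearson formula written out
  chi_oracle <- function(a, b) {
    m <- rbind(a, b)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  got <- chi2_2x2(c(840, 2160), c(900, 3600))
  expect_equal(got$statistic, chi_oracle(c(840, 2160), c(900, 3600)))
  expect_equal(got$statistic, 64.7, tolerance = 0.01)
  expect_lt(got$p, 0.01)
  eq <- chi2_2x2(c(20, 80), c(40, 160))
  expect_equal(eq$statistic, 0)
  sw <- chi2_2x2(c(900, 3600), c(840, 2160))
  expect_equal(sw$statistic, got$statistic)
  expect_error(chi2_2x2(c(0, 0), c(1, 2)), "marginal")
})

test_that("threshold sweeps match per-threshold brute force and are monotone", {
  set.seed(8)
  n <- 200
  s <- runif(n); y <- rbinom(n, 1, s)
  grp <- sample(c("Black", "White"), n, replace = TRUE)
  grid <- seq(0.05, 0.95, by = 0.05)
  sw <- threshold_sweep(s, y, grp, grid)
  for (g in c("Black", "White")) {
    m <- sw$metrics[sw$metrics$group == g, ]
    m <- m[order(m$threshold), ]
    expect_true(all(diff(m$tpr) <= 1e-12))
    expect_true(all(diff(m$fpr) <= 1e-12))
    # brute force re-count at each threshold
    for (i in seq_along(grid)) {
      sel <- grp == g
      flag <- s[sel] >= grid[i]
      expect_equal(m$tpr[i], sum(flag & y[sel] == 1) / sum(y[sel] == 1))
    }
  }
  lo <- threshold_sweep(s, y, grp, grid = 1e-9 + 1e-12)
  expect_true(all(lo$metrics$tpr == 1 & lo$metrics$fpr == 1))
  hi <- threshold_sweep(s, y, grp, grid = 1 - 1e-9)
  expect_true(all(hi$metrics$flag_rate == 0))
  expect_error(threshold_sweep(s, y, grp, grid = numeric(0)), "non-empty")
})
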