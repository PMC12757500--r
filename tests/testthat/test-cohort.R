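test_that("generator configuration invariants are enforced", {
  expect_error(generator_config(race_fractions = c(Black = 0.5, White = 0.6)),
               "sum to 1")
  expect_error(generator_config(target_event_rates = c(Black = 0, White = 0.2)),
               "strictly in")
  bad <- default_correlation_matrix()
  bad["age", "egfr"] <- 0.9 # asymmetric
  expect_error(generator_config(correlation_matrix = bad), "symmetric")
  bad <- default_correlation_matrix()
  bad["age", "egfr"] <- bad["egfr", "age"] <- 2
  expect_error(generator_config(correlation_matrix = bad), "diagonal|semi-definite")
  # a genuinely indefinite but symmetric unit-diagonal matrix
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  dimnames(bad) <- list(c("a", "b", "c"), c("a", "b", "c"))
  ev <- eigen(bad, only.values = TRUE)$values
  expect_true(min(ev) < 0) # oracle: this matrix is not PSD
  expect_error(generator_config(correlation_matrix = bad), "semi-definite")
})

test_that("calibrate_intercept hits the target and is monotone", {
  set.seed(1)
  lp <- rnorm(5000, sd = 1.4)
  for (target in c(0.28, 0.20, 0.05, 0.7)) {
    b0 <- calibrate_intercept(target, lp)
    expect_equal(mean(plogis(b0 + lp)), target, tolerance = 1e-6)
    # independent check: a grid around the root brackets the target
    expect_lt(mean(plogis(b0 - 0.01 + lp)), target)
    expect_gt(mean(plogis(b0 + 0.01 + lp)), target)
  }
  # marginal rate strictly increasing in the intercept
  grid <- seq(-3, 3, by = 0.5)
  rates <- vapply(grid, function(b) mean(plogis(b + lp)), numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_error(calibrate_intercept(0, lp), "strictly in")
  expect_error(calibrate_intercept(1, lp), "strictly in")
  expect_error(calibrate_intercept(0.5, numeric(0)), "non-empty")
})

test_that("progression_probability is logistic in the linear predictor", {
  beta <- c(x1 = 0.8, x2 = -0.5)
  z0 <- matrix(0, 1, 2, dimnames = list(NULL, c("x1", "x2")))
  expect_equal(progression_probability(z0, beta, intercept = -1), plogis(-1))
  # sign flip with symmetric features mirrors about plogis(intercept)
  z <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("x1", "x2")))
  p_pos <- progression_probability(z, beta, intercept = -1)
  p_neg <- progression_probability(-z, beta, intercept = -1)
  expect_equal(qlogis(p_pos) - (-1), -(qlogis(p_neg) - (-1)), tolerance = 1e-10)
  expect_error(progression_probability(z, c(bad = 1)), "no feature column")
})

test_that("a calibrated intercept reproduces the marginal rate on a large draw", {
  # Monte-Carlo oracle: fresh 50,000-point feature sample
  set.seed(99)
  z <- matrix(rnorm(50000 * 2), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  beta <- c(x1 = 0.9, x2 = -0.6)
  lp <- as.vector(z %*% beta)
  b0 <- calibrate_intercept(0.28, lp)
  p <- progression_probability(z, beta, intercept = b0)
  draws <- rbinom(length(p), 1, p)
  expect_equal(mean(draws), 0.28, tolerance = 0.005)
})

test_that("the composite endpoint rule follows its three clauses", {
  # sustained 42% drop: 29/50 = 0.58 <= 0.60 from year 1 onward
  expect_true(ascertain_progression(c(50, 29, 29, 29, 29, 29)))
  # flat trajectory, no failure
  expect_false(ascertain_progression(c(60, 60, 60, 60, 60, 60)))
  # two consecutive >= 5 declines (6, 6), then shallow
  expect_true(ascertain_progression(c(80, 74, 68, 66, 65, 64)))
  # single large drop, not confirmed, not sustained below 60%
  expect_false(ascertain_progression(c(80, 73, 72, 71, 70, 70)))
  # a dip below 60% that recovers is not sustained
  expect_false(ascertain_progression(c(50, 28, 45, 45, 45, 45)))
  # kidney failure alone decides
  expect_true(ascertain_progression(c(60, 60, 60, 60, 60, 60),
                                    kidney_failure_year = 3))
  expect_error(ascertain_progression(c(0, 10, 10, 10, 10, 10)), "positive")
  expect_error(ascertain_progression(c(50, 40, 30)), "6 annual values")
})

test_that("generated trajectories re-derive their label and are seed-stable", {
  for (s in 1:20) {
    for (lab in c(TRUE, FALSE)) {
      base <- runif(1, 16, 110)
      tr <- generate_trajectory(base, lab, seed = s)
      expect_identical(tr$trajectory[1], base)
      expect_equal(ascertain_progression(tr$trajectory, tr$kidney_failure_year),
                   lab)
      expect_identical(generate_trajectory(base, lab, seed = s), tr)
    }
  }
  # zero-noise non-progressor from a high baseline declines mildly
  quiet <- trajectory_params(measurement_noise_sd = 0)
  tr <- generate_trajectory(90, FALSE, params = quiet, seed = 1)
  expect_false(ascertain_progression(tr$trajectory))
  expect_true(all(diff(tr$trajectory) > -5))
  expect_error(generate_trajectory(10, TRUE), "\\[15, 120\\]")
})

test_that("cohort generation is exact in counts, deterministic, and label-consistent", {
  cfg <- generator_config(n_total = 601, biomarker_subset_size = 120, seed = 5)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 601)
  # largest-remainder stratified counts: 240.4 -> 240, 360.6 -> 361
  expect_equal(as.vector(table(cohort$race)[c("Black", "White")]), c(240, 361))
  expect_identical(generate_cohort(cfg), cohort)
  expect_equal(sum(!is.na(cohort$tnfr1)), 120)
  expect_true(all(cohort$source_cohort[!is.na(cohort$tnfr1)] == "EHR_A_like"))
  expect_true(all(cohort$uacr > 0))
  expect_true(all(cohort$age >= 18))
  expect_true(all(cohort$egfr_baseline >= 15 & cohort$egfr_baseline <= 120))
  expect_equal(cohort$egfr_y0, cohort$egfr_baseline)
  relabel <- vapply(seq_len(nrow(cohort)), function(i) {
    ascertain_progression(as.numeric(cohort[i, paste0("egfr_y", 0:5)]),
                          cohort$kidney_failure_year[i])
  }, logical(1))
  expect_identical(relabel, cohort$progression)
})

test_that("the cohort CSV round-trips", {
  cohort <- small_cohort(n = 200, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  drop <- c("risk_signal", "true_probability")
  orig <- as.data.frame(cohort)[, setdiff(names(cohort), drop)]
  expect_equal(as.data.frame(back), orig, tolerance = 1e-12,
               ignore_attr = TRUE)
  # header present and empty biomarker fields stay empty
  header <- readLines(path, n = 1)
  expect_match(header, "^\"id\",\"source_cohort\",\"race\",")
})
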