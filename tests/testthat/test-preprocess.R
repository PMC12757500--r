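toy_rows_ <- function(uacr = c(100, 50, 200), src = "NHANES_like") {
  n <- length(uacr)
  data.frame(
    id = sprintf("T%02d", seq_len(n)), source_cohort = src,
    race = "White", sex = rep_len(c("female", "male"), n),
    age = seq(40, 40 + 5 * (n - 1), by = 5),
    egfr_baseline = seq(40, 40 + 8 * (n - 1), by = 8), uacr = uacr,
    sbp = seq(120, 120 + 10 * (n - 1), by = 10), dbp = rep(80, n) + seq_len(n),
    diabetes = rep_len(c(TRUE, FALSE), n), hypertension = rep_len(c(FALSE, TRUE), n),
    cvd = FALSE, hba1c = 6 + seq_len(n) / 10, glucose = 100 + seq_len(n),
    ldl = 100 + seq_len(n), hdl = 50 + seq_len(n),
    triglycerides = 140 + seq_len(n), hemoglobin = 13 + seq_len(n) / 10,
    stringsAsFactors = FALSE
  )
}

test_that("imputation, z-scoring and the log-UACR transform follow the contract", {
  rows <- toy_rows_()
  rows$hba1c <- c(1, 2, NA) + 5 # values 6, 7, NA -> impute 6.5
  st <- fit_preprocessor(rows)
  expect_equal(unname(st$stats$NHANES_like$impute["hba1c"]), 6.5)
  x <- apply_preprocessor(st, rows)
  # imputed value equals the observed mean before scaling, i.e. z of 6.5
  expect_equal(x[3, "hba1c"],
               (6.5 - st$stats$NHANES_like$means[["hba1c"]]) /
                 st$stats$NHANES_like$sds[["hba1c"]], ignore_attr = TRUE)
  # z-score on [2, 4, 6]-style columns: mean 0, sd 1
  expect_equal(unname(colMeans(x[, c("age", "sbp", "glucose")])), rep(0, 3),
               tolerance = 1e-12)
  expect_equal(unname(apply(x[, c("age", "sbp", "glucose")], 2, sd)), rep(1, 3),
               tolerance = 1e-12)
  # UACR of 100 is ln(100) before scaling
  expect_equal(x[1, "log_uacr"] * st$stats$NHANES_like$sds[["log_uacr"]] +
                 st$stats$NHANES_like$means[["log_uacr"]],
               log(100), ignore_attr = TRUE)
  # binary features pass through untouched
  expect_equal(unname(x[, "diabetes"]), c(1, 0, 1))
  expect_equal(unname(x[, "sex"]), c(1, 0, 1))
})

test_that("values outside the plausibility bounds are clamped before scaling", {
  rows <- toy_rows_(uacr = c(100, 50, 50000)) # above the 10,000 mg/g bound
  rows$sbp <- c(120, 400, 130)                # above the 250 mmHg bound
  st <- fit_preprocessor(rows)
  x <- apply_preprocessor(st, rows)
  stn <- st$stats$NHANES_like
  expect_equal(x[3, "log_uacr"] * stn$sds[["log_uacr"]] + stn$means[["log_uacr"]],
               log(10000), ignore_attr = TRUE)
  expect_equal(x[2, "sbp"] * stn$sds[["sbp"]] + stn$means[["sbp"]], 250,
               ignore_attr = TRUE)
})

test_that("the preprocessor state is a pure function of the training rows", {
  cohort <- small_cohort(n = 300, seed = 21)
  train <- cohort[1:200, ]
  test <- cohort[201:300, ]
  st <- fit_preprocessor(train)
  # mutating test rows cannot change the state or the training transform
  test2 <- test
  test2$uacr <- test2$uacr * 10
  test2$sbp <- test2$sbp + 40
  expect_identical(fit_preprocessor(train), st)
  x1 <- apply_preprocessor(st, test)
  x2 <- apply_preprocessor(st, test2)
  expect_identical(x1[, "age"], x2[, "age"]) # untouched columns unaffected
  # test rows are scaled by training statistics, not their own
  expect_false(isTRUE(all.equal(mean(x1[, "egfr_baseline"]), 0, tolerance = 1e-6)))
  # refitting on the transform of the fit rows is idempotent in statistics
  x_train <- apply_preprocessor(st, train)
  for (src in names(st$stats)) {
    idx <- train$source_cohort == src
    expect_equal(unname(colMeans(x_train[idx, st$continuous, drop = FALSE])),
                 rep(0, length(st$continuous)), tolerance = 1e-10)
  }
})

test_that("row order permutes through the pipeline without interaction", {
  cohort <- small_cohort(n = 150, seed = 22)
  st <- fit_preprocessor(cohort)
  x <- apply_preprocessor(st, cohort)
  perm <- sample(nrow(cohort))
  xp <- apply_preprocessor(st, cohort[perm, ])
  expect_equal(xp, x[perm, ], ignore_attr = TRUE)
})

test_that("degenerate training inputs raise named errors", {
  rows <- toy_rows_()
  rows$hba1c <- NA_real_
  expect_error(fit_preprocessor(rows), "hba1c")
  rows <- toy_rows_()
  rows$glucose <- 100
  expect_error(fit_preprocessor(rows), "glucose")
  st <- fit_preprocessor(toy_rows_())
  other <- toy_rows_(src = "CRIC_like")
  expect_error(apply_preprocessor(st, other), "CRIC_like")
  expect_error(fit_preprocessor(toy_rows_()[0, ]), "non-empty")
})
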