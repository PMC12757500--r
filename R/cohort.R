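# Synthetic cohort generation: correlated latent covariates mapped to the
# clinical scale, a per-race logistic outcome model with calibrated
# intercepts, and eGFR trajectories constructed to re-derive the assigned
# progression label under the composite endpoint rule.

#' Intercept that hits a target marginal event rate
#'
#' Solves (by bracketed root finding) for the intercept `b0` such that
#' `mean(plogis(b0 + lp))` equals `target_rate`, where `lp` is a sample of
#' linear predictors without intercept. Used by the cohort generator to pin
#' per-race marginal progression rates, and by the model-recalibration step
#' to undo the upward shift induced by class weighting and oversampling.
#'
#' @param target_rate Target marginal probability, strictly in (0, 1).
#' @param lp Numeric vector of linear predictors (no intercept).
#' @param bracket Half-width of the search bracket in logits (default 20).
#' @return The intercept (a single number); the achieved marginal rate is
#'   within 1e-6 of the target.
#' @export
calibrate_intercept <- function(target_rate, lp, bracket = 20) {
  if (length(target_rate) != 1 || !is.finite(target_rate) ||
      target_rate <= 0 || target_rate >= 1) {
    stop("target_rate must lie strictly in (0, 1)")
  }
  if (length(lp) == 0) stop("lp must be a non-empty numeric vector")
  f <- function(b0) mean(plogis(b0 + lp)) - target_rate
  if (f(-bracket) > 0 || f(bracket) < 0) {
    stop("no intercept within +/-", bracket, " logits achieves the target rate")
  }
  uniroot(f, c(-bracket, bracket), tol = 1e-10)$root
}

#' Per-patient progression probability under the generator's outcome model
#'
#' Logistic model on standardized (latent-scale) features:
#' `plogis(intercept + sum(coefficients * features))`. Features and
#' coefficients are matched by name; a coefficient without a matching
#' feature column is an error.
#'
#' @param features Numeric matrix (patients x latent features) with column
#'   names, on the standardized scale.
#' @param coefficients Named numeric vector of log-odds weights.
#' @param intercept Model intercept (log-odds).
#' @return Vector of probabilities in (0, 1).
#' @export
progression_probability <- function(features, coefficients, intercept = 0) {
  missing_feat <- setdiff(names(coefficients), colnames(features))
  if (length(missing_feat) > 0) {
    stop("no feature column for coefficient(s): ",
         paste(missing_feat, collapse = ", "))
  }
  lp <- as.vector(features[, names(coefficients), drop = FALSE] %*% coefficients)
  plogis(intercept + lp)
}

#' Composite five-year CKD progression endpoint
#'
#' A patient progresses if any of: (a) a sustained >= 40% eGFR drop from
#' baseline, operationalized as some annual value falling to <= 60% of
#' baseline with every later value also staying at or below that level;
#' (b) a confirmed annual eGFR decline of >= 5 ml/min/1.73 m\eqn{^2} in two
#' consecutive year-to-year intervals; or (c) a kidney-failure event
#' (dialysis or transplant listing) in years 1-5.
#'
#' @param trajectory Numeric vector of 6 annual eGFR values (years 0-5);
#'   the first entry is baseline and must be positive.
#' @param kidney_failure_year Year (1-5) of a kidney-failure event, or
#'   `NA`/`NULL` if none occurred.
#' @return `TRUE` if the composite endpoint is met.
#' @export
ascertain_progression <- function(trajectory, kidney_failure_year = NA) {
  if (length(trajectory) != 6) stop("trajectory must hold 6 annual values")
  baseline <- trajectory[1]
  if (!is.finite(baseline) || baseline <= 0) stop("baseline eGFR must be positive")
  if (!is.null(kidney_failure_year) && !is.na(kidney_failure_year) &&
      kidney_failure_year >= 1 && kidney_failure_year <= 5) {
    return(TRUE)
  }
  thr <- 0.6 * baseline
  below <- trajectory[-1] <= thr
  # sustained: once reached, stays at or below through year 5
  sustained <- any(vapply(seq_along(below), function(k) all(below[k:length(below)]),
                          logical(1)))
  if (sustained) return(TRUE)
  declines <- -diff(trajectory)
  confirmed <- any(declines[-length(declines)] >= 5 & declines[-1] >= 5)
  confirmed
}

#' Simulate an eGFR trajectory consistent with a progression label
#'
#' Draws a linear annual decline (slope distribution depending on the
#' label) plus measurement noise, floored at zero, with `trajectory[1]`
#' fixed at baseline; progressors may additionally receive a
#' kidney-failure year from a per-year hazard. Noise draws are rejected
#' and redrawn (up to `max_tries`) until [ascertain_progression()] applied
#' to the result returns the input label; if no noisy draw qualifies, the
#' noise-free trajectory (which qualifies by construction under the
#' default slopes) is used.
#'
#' @param egfr_baseline Baseline eGFR in [15, 120].
#' @param progression Logical label the trajectory must re-derive.
#' @param params See [trajectory_params()].
#' @param seed Optional seed for a self-contained draw; when `NULL` the
#'   current RNG stream is used (as inside [generate_cohort()]).
#' @param max_tries Rejection-sampling budget (default 25).
#' @return A list with `trajectory` (6 values) and `kidney_failure_year`
#'   (`NA` when no failure event).
#' @export
generate_trajectory <- function(egfr_baseline, progression,
                                params = trajectory_params(),
                                seed = NULL, max_tries = 25) {
  if (egfr_baseline < 15 || egfr_baseline > 120) {
    stop("egfr_baseline must lie in [15, 120]")
  }
  draw <- function() {
    failure_year <- NA_real_
    if (progression) {
      slope <- rnorm(1, params$progressor_slope_mean, params$progressor_slope_sd)
      fails <- runif(5) < params$failure_hazard_given_progressor
      if (any(fails)) failure_year <- which(fails)[1]
    } else {
      slope <- rnorm(1, params$nonprogressor_slope_mean, params$nonprogressor_slope_sd)
    }
    for (try in seq_len(max_tries)) {
      noise <- c(0, rnorm(5, 0, params$measurement_noise_sd))
      traj <- pmax(0, egfr_baseline + slope * 0:5 + noise)
      traj[1] <- egfr_baseline
      if (!progression) traj <- pmax(traj, 1e-6) # keep non-progressors positive
      if (ascertain_progression(traj, failure_year) == progression) {
        return(list(trajectory = traj, kidney_failure_year = failure_year))
      }
    }
    # noise-free fallback: default slopes satisfy the rule deterministically
    slope0 <- if (progression) params$progressor_slope_mean else
      params$nonprogressor_slope_mean
    traj <- pmax(0, egfr_baseline + slope0 * 0:5)
    if (!progression) traj <- pmax(traj, 1e-6)
    list(trajectory = traj, kidney_failure_year = failure_year)
  }
  if (is.null(seed)) draw() else with_seed_(seed, draw())
}

# Draw one race stratum: latent MVN covariates, clinical-scale mapping,
# outcome assignment with calibrated intercept, trajectories.
generate_stratum_ <- function(race, n, config) {
  R <- config$correlation_matrix
  L <- chol(R + diag(1e-10, nrow(R)))
  z <- matrix(rnorm(n * nrow(R)), n, nrow(R)) %*% L
  colnames(z) <- colnames(R)
  cv <- config$covariates[[race]]

  sex <- ifelse(runif(n) < 0.5, "female", "male")
  clin <- function(name) cv$means[[name]] + cv$sds[[name]] * z[, name]
  age <- pmax(18, clin("age"))
  egfr <- pmin(120, pmax(15, clin("egfr")))
  uacr <- exp(log(cv$uacr_median) + cv$uacr_log_sd * z[, "log_uacr"])
  comorb <- function(name) z[, name] > qnorm(1 - cv$prevalence[[name]])

  frailty <- rnorm(n)
  feats <- cbind(z, frailty = frailty)
  beta <- config$outcome_coefficients[[race]]
  lp <- as.vector(feats[, names(beta), drop = FALSE] %*% beta)
  intercept <- calibrate_intercept(config$target_event_rates[[race]], lp)
  p <- plogis(intercept + lp)
  progression <- runif(n) < p

  traj <- matrix(NA_real_, n, 6)
  failure_year <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- generate_trajectory(egfr[i], progression[i], config$trajectory)
    traj[i, ] <- tr$trajectory
    failure_year[i] <- tr$kidney_failure_year
  }

  risk_sig <- as.vector(scale(lp)) # standardized latent risk, frailty included
  data.frame(
    race = race,
    sex = sex,
    age = age,
    serum_creatinine = invert_ckd_epi_2021(egfr, age, sex),
    egfr_baseline = egfr,
    uacr = uacr,
    sbp = clin("sbp"),
    dbp = clin("dbp"),
    diabetes = comorb("diabetes"),
    hypertension = comorb("hypertension"),
    cvd = comorb("cvd"),
    hba1c = clin("hba1c"),
    glucose = clin("glucose"),
    ldl = clin("ldl"),
    hdl = pmax(10, clin("hdl")),
    triglycerides = pmax(30, clin("triglycerides")),
    total_cholesterol = clin("total_cholesterol"),
    hemoglobin = clin("hemoglobin"),
    risk_signal = risk_sig,
    true_probability = p,
    egfr_y0 = traj[, 1], egfr_y1 = traj[, 2], egfr_y2 = traj[, 3],
    egfr_y3 = traj[, 4], egfr_y4 = traj[, 5], egfr_y5 = traj[, 6],
    kidney_failure_year = failure_year,
    progression = progression,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic race-structured CKD cohort
#'
#' Produces a patient-level cohort under a fixed seed: exact (stratified)
#' race counts, correlated clinical covariates mapped from a latent
#' Gaussian scale, per-race logistic progression outcomes whose intercepts
#' are calibrated to the configured marginal rates, eGFR trajectories that
#' re-derive each label under [ascertain_progression()], and plasma
#' biomarkers (TNFR1/TNFR2/KIM-1) for a designated sub-cohort labeled
#' `EHR_A_like`.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` of class `ckd_cohort`, one row per patient, with
#'   the documented cohort CSV schema (see [write_cohort()]).
#' @examples
#' cohort <- generate_cohort(generator_config(n_total = 300,
#'                                            biomarker_subset_size = 60))
#' table(cohort$race)
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "ckd_generator_config"))
  races <- names(config$race_fractions)
  counts <- floor(config$n_total * config$race_fractions)
  # largest-remainder rounding so counts are exact and sum to n_total
  rem <- config$n_total * config$race_fractions - counts
  short <- config$n_total - sum(counts)
  if (short > 0) {
    counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  }
  cohort <- with_seed_(config$seed, {
    strata <- lapply(races, function(r) generate_stratum_(r, counts[[r]], config))
    out <- do.call(rbind, strata)
    out$id <- sprintf("P%05d", seq_len(nrow(out)))
    # biomarker sub-cohort drawn at random across races; remainder split
    # among the survey/cohort-like sources
    n <- nrow(out)
    bio_idx <- sort(sample.int(n, config$biomarker_subset_size))
    src <- sample(c("NHANES_like", "CRIC_like", "UKB_like"), n,
                  replace = TRUE, prob = c(0.4, 0.3, 0.3))
    src[bio_idx] <- "EHR_A_like"
    out$source_cohort <- src
    out$tnfr1 <- out$tnfr2 <- out$kim1 <- NA_real_
    lmu <- c(tnfr1 = log(2400), tnfr2 = log(9000), kim1 = log(300))
    for (bm in names(lmu)) {
      out[[bm]][bio_idx] <- exp(
        lmu[[bm]] +
          config$biomarker_loading * out$risk_signal[bio_idx] +
          config$biomarker_noise_sd * rnorm(length(bio_idx))
      )
    }
    out
  })
  cols <- c("id", "source_cohort", "race", "sex", "age", "serum_creatinine",
            "egfr_baseline", "uacr", "sbp", "dbp", "diabetes", "hypertension",
            "cvd", "hba1c", "glucose", "ldl", "hdl", "triglycerides",
            "total_cholesterol", "hemoglobin", "tnfr1", "tnfr2", "kim1",
            paste0("egfr_y", 0:5), "kidney_failure_year", "progression",
            "risk_signal", "true_probability")
  cohort <- cohort[, cols]
  rownames(cohort) <- NULL
  class(cohort) <- c("ckd_cohort", "data.frame")
  attr(cohort, "seed") <- config$seed
  cohort
}

#' Write / read the cohort CSV
#'
#' One row per patient, header mandatory, UTF-8, `.` decimal separator;
#' logical columns are stored as 0/1 and missing biomarkers as empty
#' fields. `read_cohort()` restores column types and the `ckd_cohort`
#' class. The internal simulation truth columns (`risk_signal`,
#' `true_probability`) are excluded from the file.
#'
#' @param cohort A `ckd_cohort` data frame.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$risk_signal <- NULL
  out$true_probability <- NULL
  for (col in c("diabetes", "hypertension", "cvd", "progression")) {
    out[[col]] <- as.integer(out[[col]])
  }
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("diabetes", "hypertension", "cvd", "progression")) {
    out[[col]] <- as.logical(out[[col]])
  }
  class(out) <- c("ckd_cohort", "data.frame")
  out
}
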