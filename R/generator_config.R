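# Configuration objects for the synthetic CKD cohort generator.
#
# Defaults emulate the published summary characteristics of a pooled
# NHANES/CRIC/UK-Biobank-like stage 1-4 CKD cohort: 7,500 adults, 40%
# Black / 60% White, baseline eGFR means ~45 vs ~48 ml/min/1.73m2, UACR
# medians ~120 vs ~60 mg/g, diabetes prevalence 45% vs 40%, and five-year
# progression rates of 28% vs 20%.

latent_names_ <- function() {
  c("age", "egfr", "log_uacr", "sbp", "dbp", "hba1c", "glucose",
    "ldl", "hdl", "triglycerides", "hemoglobin", "total_cholesterol",
    "diabetes", "hypertension", "cvd")
}

#' Default latent-scale correlation matrix for cohort simulation
#'
#' Correlations among the latent standard-normal drivers of the clinical
#' covariates (continuous labs plus the latent liabilities behind the
#' binary comorbidities). Values encode familiar clinical structure:
#' eGFR falls with age and albuminuria, glycemic markers cluster with the
#' diabetes liability, pressures cluster with the hypertension liability,
#' lipid fractions cluster with total cholesterol. The matrix is symmetric
#' positive semi-definite with unit diagonal.
#'
#' @return A 15 x 15 named correlation matrix.
#' @export
default_correlation_matrix <- function() {
  nm <- latent_names_()
  R <- diag(length(nm))
  dimnames(R) <- list(nm, nm)
  set_cor <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_cor("age", "egfr", -0.30)
  set_cor("age", "sbp", 0.25)
  set_cor("age", "cvd", 0.20)
  set_cor("egfr", "log_uacr", -0.35)
  set_cor("egfr", "hemoglobin", 0.30)
  set_cor("log_uacr", "diabetes", 0.30)
  set_cor("log_uacr", "sbp", 0.20)
  set_cor("sbp", "dbp", 0.60)
  set_cor("sbp", "hypertension", 0.50)
  set_cor("sbp", "cvd", 0.15)
  set_cor("dbp", "hypertension", 0.35)
  set_cor("hba1c", "glucose", 0.60)
  set_cor("hba1c", "diabetes", 0.55)
  set_cor("glucose", "diabetes", 0.50)
  set_cor("ldl", "total_cholesterol", 0.75)
  set_cor("hdl", "total_cholesterol", 0.20)
  set_cor("triglycerides", "total_cholesterol", 0.35)
  set_cor("triglycerides", "hdl", -0.30)
  set_cor("cvd", "diabetes", 0.20)
  R
}

default_covariates_ <- function() {
  # means/sds on the clinical scale per race; UACR is parameterized by its
  # median and log-scale sd (log-normal)
  list(
    Black = list(
      means = c(age = 58, egfr = 45, sbp = 137, dbp = 82, hba1c = 6.6,
                glucose = 122, ldl = 106, hdl = 50, triglycerides = 145,
                hemoglobin = 12.7, total_cholesterol = 186),
      sds = c(age = 12, egfr = 15, sbp = 16, dbp = 10, hba1c = 1.3,
              glucose = 34, ldl = 32, hdl = 14, triglycerides = 70,
              hemoglobin = 1.7, total_cholesterol = 38),
      uacr_median = 120, uacr_log_sd = 1.3,
      prevalence = c(diabetes = 0.45, hypertension = 0.75, cvd = 0.22)
    ),
    White = list(
      means = c(age = 61, egfr = 48, sbp = 133, dbp = 80, hba1c = 6.6,
                glucose = 116, ldl = 110, hdl = 52, triglycerides = 150,
                hemoglobin = 13.1, total_cholesterol = 190),
      sds = c(age = 12, egfr = 15, sbp = 15, dbp = 10, hba1c = 1.2,
              glucose = 30, ldl = 33, hdl = 14, triglycerides = 75,
              hemoglobin = 1.6, total_cholesterol = 38),
      uacr_median = 60, uacr_log_sd = 1.3,
      prevalence = c(diabetes = 0.40, hypertension = 0.70, cvd = 0.18)
    )
  )
}

default_outcome_coefficients_ <- function() {
  # Log-odds weights on the latent (standardized) covariate scale, plus a
  # "frailty" weight on an unobserved risk factor that the plasma
  # biomarkers tap. The Black stratum carries heavier albuminuria and
  # blood-pressure weights, so a race-blind model fitted to the pooled
  # cohort miscalibrates by group.
  list(
    Black = c(egfr = -0.90, log_uacr = 0.95, sbp = 0.55, hba1c = 0.40,
              age = 0.25, diabetes = 0.30, hemoglobin = -0.20,
              frailty = 0.85),
    White = c(egfr = -0.70, log_uacr = 0.10, sbp = 0.10, hba1c = 0.55,
              age = 0.55, diabetes = 0.45, hemoglobin = -0.10,
              frailty = 0.85)
  )
}

#' Default eGFR-trajectory parameters
#'
#' Annual eGFR slopes (ml/min/1.73 m\eqn{^2}/yr) for progressors and
#' non-progressors, measurement noise, and the per-year kidney-failure
#' hazard among progressors. The progressor slope mean of -7 comfortably
#' exceeds the composite endpoint's confirmed >= 5/yr decline criterion.
#'
#' @return A list of trajectory parameters.
#' @export
trajectory_params <- function(progressor_slope_mean = -7,
                              progressor_slope_sd = 1.5,
                              nonprogressor_slope_mean = -1,
                              nonprogressor_slope_sd = 1,
                              measurement_noise_sd = 1.5,
                              failure_hazard_given_progressor = 0.06) {
  if (progressor_slope_mean > -5) {
    stop("progressor_slope_mean must be <= -5 (endpoint decline criterion)")
  }
  if (measurement_noise_sd < 0) stop("measurement_noise_sd must be >= 0")
  list(
    progressor_slope_mean = progressor_slope_mean,
    progressor_slope_sd = progressor_slope_sd,
    nonprogressor_slope_mean = nonprogressor_slope_mean,
    nonprogressor_slope_sd = nonprogressor_slope_sd,
    measurement_noise_sd = measurement_noise_sd,
    failure_hazard_given_progressor = failure_hazard_given_progressor
  )
}

#' Configuration for the synthetic CKD cohort generator
#'
#' Bundles and validates every knob of the simulator: cohort size and race
#' mix, per-race covariate means/sds (with UACR as a log-normal given its
#' median), the latent correlation matrix, comorbidity prevalences,
#' per-race outcome coefficient vectors with marginal event-rate targets,
#' the biomarker sub-cohort size and loading, and trajectory parameters.
#'
#' @param n_total Cohort size (default 7,500).
#' @param race_fractions Named fractions summing to 1 (default 40% Black,
#'   60% White; race counts are exact, not sampled).
#' @param target_event_rates Named per-race five-year progression rates in
#'   (0,1); intercepts are calibrated so the simulated marginal rates match.
#' @param covariates Per-race covariate specification (means, sds, UACR
#'   median/log-sd, comorbidity prevalences).
#' @param correlation_matrix Latent-scale correlation matrix; must be
#'   symmetric positive semi-definite with unit diagonal.
#' @param outcome_coefficients Per-race named log-odds weights on the
#'   latent covariates plus a `frailty` weight.
#' @param risk_scale Multiplier applied to all outcome coefficients; tunes
#'   the overall strength of the covariate-outcome signal.
#' @param biomarker_subset_size Number of patients (labeled `EHR_A_like`)
#'   carrying TNFR1/TNFR2/KIM-1 measurements (default 1,200).
#' @param biomarker_loading Loading of standardized latent risk on the
#'   log-scale biomarkers.
#' @param biomarker_noise_sd Independent log-scale biomarker noise.
#' @param trajectory Trajectory parameters, see [trajectory_params()].
#' @param seed Integer RNG seed (default 42).
#' @return An object of class `ckd_generator_config`.
#' @export
generator_config <- function(n_total = 7500,
                             race_fractions = c(Black = 0.4, White = 0.6),
                             target_event_rates = c(Black = 0.28, White = 0.20),
                             covariates = default_covariates_(),
                             correlation_matrix = default_correlation_matrix(),
                             outcome_coefficients = default_outcome_coefficients_(),
                             risk_scale = 1,
                             biomarker_subset_size = 1200,
                             biomarker_loading = 0.55,
                             biomarker_noise_sd = 0.5,
                             trajectory = trajectory_params(),
                             seed = 42) {
  if (!is.numeric(n_total) || n_total < 1) stop("n_total must be >= 1")
  if (is.null(names(race_fractions)) || any(!nzchar(names(race_fractions)))) {
    stop("race_fractions must be named")
  }
  if (abs(sum(race_fractions) - 1) > 1e-8) {
    stop("race_fractions must sum to 1")
  }
  races <- names(race_fractions)
  if (!all(races %in% names(target_event_rates))) {
    stop("target_event_rates must cover every race in race_fractions")
  }
  if (any(target_event_rates <= 0 | target_event_rates >= 1)) {
    stop("target_event_rates must lie strictly in (0, 1)")
  }
  R <- correlation_matrix
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10))) {
    stop("correlation_matrix must be symmetric")
  }
  if (any(abs(diag(R) - 1) > 1e-10)) {
    stop("correlation_matrix must have unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation_matrix must be positive semi-definite")
  }
  if (!all(races %in% names(covariates)) ||
      !all(races %in% names(outcome_coefficients))) {
    stop("covariates and outcome_coefficients must cover every race")
  }
  if (biomarker_subset_size > n_total) {
    stop("biomarker_subset_size cannot exceed n_total")
  }
  structure(
    list(
      n_total = as.integer(n_total),
      race_fractions = race_fractions,
      target_event_rates = target_event_rates,
      covariates = covariates,
      correlation_matrix = R,
      outcome_coefficients = lapply(outcome_coefficients, function(b) b * risk_scale),
      biomarker_subset_size = as.integer(biomarker_subset_size),
      biomarker_loading = biomarker_loading,
      biomarker_noise_sd = biomarker_noise_sd,
      trajectory = trajectory,
      seed = as.integer(seed)
    ),
    class = "ckd_generator_config"
  )
}
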