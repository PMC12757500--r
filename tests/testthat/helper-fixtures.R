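# Shared fixtures: a memoized default-configuration run (used by the
# end-to-end tests so the cohort and cross-validated models are built
# once per session) and small fast configurations for property tests.

.ckdfair_cache <- new.env(parent = emptyenv())

cached_ <- function(key, expr) {
  if (!exists(key, envir = .ckdfair_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .ckdfair_cache)
  }
  get(key, envir = .ckdfair_cache, inherits = FALSE)
}

default_cohort_cached <- function() {
  cached_("cohort", generate_cohort(generator_config()))
}

default_oof_cached <- function(strategy) {
  cached_(paste0("oof_", strategy),
          run_strategy(default_cohort_cached(), strategy))
}

# small cohort for unit/property tests
small_cohort <- function(n = 600, seed = 7, ...) {
  generate_cohort(generator_config(n_total = n,
                                   biomarker_subset_size = min(120L, n),
                                   seed = seed, ...))
}

# reduced training budget for tests that need many model fits
fast_mlp_config <- function(seed = 42, ...) {
  mlp_config(max_epochs = 15, patience = 4, seed = seed, ...)
}

# generator in which both races share covariate distributions, outcome
# coefficients and event rates (homogeneous data-generating process)
homogeneous_config <- function(n = 1500, seed = 11) {
  cov_w <- ckdfair:::default_covariates_()$White
  beta <- ckdfair:::default_outcome_coefficients_()$White
  generator_config(
    n_total = n,
    covariates = list(Black = cov_w, White = cov_w),
    outcome_coefficients = list(Black = beta, White = beta),
    target_event_rates = c(Black = 0.24, White = 0.24),
    biomarker_subset_size = 0,
    seed = seed
  )
}
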