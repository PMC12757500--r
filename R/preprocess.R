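# Fold-safe preprocessing: winsorize -> log-UACR -> mean-impute ->
# center/scale, with all statistics fit per source cohort on training rows
# only so no test-fold information leaks into the model.

#' The model feature sets
#'
#' `clinical_features()` returns the 15 predictors used by the base
#' models: age, sex, baseline eGFR, log-UACR, systolic and diastolic blood
#' pressure, diabetes, hypertension, cardiovascular disease, HbA1c,
#' glucose, LDL, HDL, triglycerides and hemoglobin. Total cholesterol is
#' carried in the cohort schema but not modeled; race is never a feature.
#' `biomarker_features()` appends TNFR1, TNFR2 and KIM-1 (18 features).
#'
#' @return Character vector of feature names.
#' @export
clinical_features <- function() {
  c("age", "sex", "egfr_baseline", "log_uacr", "sbp", "dbp",
    "diabetes", "hypertension", "cvd", "hba1c", "glucose",
    "ldl", "hdl", "triglycerides", "hemoglobin")
}

#' @rdname clinical_features
#' @export
biomarker_features <- function() {
  c(clinical_features(), "tnfr1", "tnfr2", "kim1")
}

binary_features_ <- function() c("sex", "diabetes", "hypertension", "cvd")

#' Default winsorization bounds for laboratory and vital-sign values
#'
#' Fixed physiologic plausibility ranges; values outside are clamped to
#' the nearest bound before any transformation. UACR bounds apply on the
#' raw (mg/g) scale, before the log transform.
#'
#' @return Named list of `c(lower, upper)` bounds.
#' @export
default_winsor_bounds <- function() {
  list(
    age = c(18, 105),
    egfr_baseline = c(5, 150),
    uacr = c(1, 10000),
    sbp = c(70, 250),
    dbp = c(30, 150),
    hba1c = c(3.5, 18),
    glucose = c(40, 800),
    ldl = c(20, 400),
    hdl = c(10, 150),
    triglycerides = c(30, 2000),
    hemoglobin = c(4, 22),
    tnfr1 = c(100, 50000),
    tnfr2 = c(100, 80000),
    kim1 = c(5, 20000)
  )
}

# winsorize + log-UACR + binary coding, no data-derived statistics
transform_raw_ <- function(rows, features, bounds) {
  clamp <- function(x, b) pmin(b[2], pmax(b[1], x))
  out <- data.frame(row.names = seq_len(nrow(rows)))
  for (f in features) {
    if (f == "log_uacr") {
      out[[f]] <- log(clamp(rows$uacr, bounds$uacr))
    } else if (f == "sex") {
      out[[f]] <- as.numeric(normalize_sex_(rows$sex) == "female")
    } else if (f %in% binary_features_()) {
      v <- as.numeric(rows[[f]])
      v[is.na(v)] <- 0 # missing comorbidity coded as absent
      out[[f]] <- v
    } else {
      if (is.null(rows[[f]])) stop("unknown column: ", f)
      v <- rows[[f]]
      if (!is.null(bounds[[f]])) v <- clamp(v, bounds[[f]])
      out[[f]] <- v
    }
  }
  out
}

#' Fit preprocessing statistics on training rows
#'
#' Computes, separately within each source cohort present in the training
#' rows, the per-feature means, standard deviations and mean-imputation
#' values of the winsorized (and for UACR, log-transformed) continuous
#' features. Binary indicators pass through unscaled, with missing values
#' coded as absent. The returned state is a pure function of the training
#' rows: applying it never uses any statistic of the rows being
#' transformed.
#'
#' @param rows Training-fold patient rows (cohort schema).
#' @param features Feature set, default [clinical_features()].
#' @param bounds Winsorization bounds, default [default_winsor_bounds()].
#' @return An object of class `ckd_preprocessor`.
#' @export
fit_preprocessor <- function(rows, features = clinical_features(),
                             bounds = default_winsor_bounds()) {
  if (nrow(rows) == 0) stop("training rows must be non-empty")
  continuous <- setdiff(features, binary_features_())
  cohorts <- unique(rows$source_cohort)
  stats <- lapply(cohorts, function(src) {
    tr <- transform_raw_(rows[rows$source_cohort == src, , drop = FALSE],
                         features, bounds)
    impute <- means <- sds <- setNames(numeric(length(continuous)), continuous)
    for (f in continuous) {
      v <- tr[[f]]
      obs <- v[!is.na(v)]
      if (length(obs) == 0) {
        stop("feature entirely missing in training rows: ", f,
             " (cohort ", src, ")")
      }
      impute[f] <- mean(obs)
      v[is.na(v)] <- impute[f]
      means[f] <- mean(v)
      sds[f] <- sd(v)
      if (!is.finite(sds[f]) || sds[f] <= 0) {
        stop("feature has zero variance in training rows: ", f,
             " (cohort ", src, ")")
      }
    }
    list(impute = impute, means = means, sds = sds)
  })
  names(stats) <- cohorts
  structure(
    list(features = features, continuous = continuous,
         bounds = bounds, stats = stats),
    class = "ckd_preprocessor"
  )
}

#' Apply fitted preprocessing to patient rows
#'
#' Applies, in order: winsorization, log-UACR, mean imputation and
#' centering/scaling, using only the statistics stored in `state` (matched
#' by each row's source cohort). Deterministic; the output matrix has no
#' missing values and a stable column order.
#'
#' @param state A fitted [fit_preprocessor()] state.
#' @param rows Patient rows sharing the cohort schema.
#' @return Numeric matrix (patients x features) with patient ids as row
#'   names.
#' @export
apply_preprocessor <- function(state, rows) {
  stopifnot(inherits(state, "ckd_preprocessor"))
  unseen <- setdiff(unique(rows$source_cohort), names(state$stats))
  if (length(unseen) > 0) {
    stop("source cohort(s) not present at fit time: ",
         paste(unseen, collapse = ", "))
  }
  tr <- transform_raw_(rows, state$features, state$bounds)
  x <- as.matrix(tr[, state$features, drop = FALSE])
  for (src in unique(rows$source_cohort)) {
    idx <- which(rows$source_cohort == src)
    st <- state$stats[[src]]
    for (f in state$continuous) {
      v <- x[idx, f]
      v[is.na(v)] <- st$impute[f]
      x[idx, f] <- (v - st$means[f]) / st$sds[f]
    }
  }
  if (anyNA(x)) stop("missing values remain after preprocessing")
  rownames(x) <- rows$id
  x
}
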