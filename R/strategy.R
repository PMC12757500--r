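# Cross-validated training of the pooled (race-blind) and modular
# (race-specific) strategies, producing strictly out-of-fold predictions.
# All preprocessing, the validation carve-out, oversampling and the
# intercept recalibration operate inside each training fold only.

# stratified carve of a validation subset (by outcome) from a training
# portion; returns logical "is validation row"
carve_validation_ <- function(outcome, fraction, seed) {
  is_val <- logical(length(outcome))
  with_seed_(seed, {
    for (cls in unique(outcome)) {
      idx <- which(outcome == cls)
      n_val <- max(1L, round(length(idx) * fraction))
      is_val[idx[sample.int(length(idx), n_val)]] <- TRUE
    }
  })
  is_val
}

# fit one fold model: preprocess -> carve validation -> oversample ->
# train -> recalibrate to the training-portion event rate
fit_fold_model_ <- function(train_rows, features, config, seed) {
  cfg <- config
  cfg$seed <- seed
  pre <- fit_preprocessor(train_rows, features)
  x_all <- apply_preprocessor(pre, train_rows)
  y_all <- as.numeric(train_rows$progression)
  is_val <- carve_validation_(y_all, cfg$validation_fraction,
                              child_seed_(seed, 7L))
  fit_idx <- which(!is_val)
  expanded <- oversample_duplicate(fit_idx, y_all[fit_idx], cfg$oversample_factor)
  model <- train_mlp(x_all[expanded, , drop = FALSE], y_all[expanded], cfg,
                     x_val = x_all[is_val, , drop = FALSE],
                     y_val = y_all[is_val])
  model <- recalibrate_model(model, x_all, mean(y_all),
                             x_val = x_all[is_val, , drop = FALSE],
                             y_val = y_all[is_val])
  list(model = model, preprocessor = pre)
}

#' Train a modeling strategy under stratified cross-validation
#'
#' Runs 5-fold (by default) stratified cross-validation of either the
#' pooled strategy (one race-blind model per fold, race never a feature)
#' or the modular strategy (per fold, one model per race trained only on
#' that race's training rows, each patient scored by their own race's
#' model). Preprocessing, the early-stopping validation carve-out,
#' minority-class oversampling and the intercept recalibration are all fit
#' within each training fold, so every returned prediction is strictly
#' out-of-fold.
#'
#' @param cohort A `ckd_cohort` data frame.
#' @param strategy `"pooled"` or `"modular"`.
#' @param config An [mlp_config()]; its seed anchors fold assignment and
#'   all per-fold model seeds.
#' @param k Number of folds (default 5).
#' @param features Feature set (default [clinical_features()]).
#' @param variant Label recorded in the output (default `"clinical"`).
#' @return A data frame of out-of-fold predictions with columns `id`,
#'   `race`, `outcome`, `fold`, `strategy`, `variant`, `risk`; every
#'   patient appears exactly once.
#' @export
run_strategy <- function(cohort, strategy = c("pooled", "modular"),
                         config = mlp_config(), k = 5,
                         features = clinical_features(),
                         variant = "clinical") {
  strategy <- match.arg(strategy)
  folds <- make_cv_folds(cohort$progression, cohort$race, k = k,
                         seed = config$seed)
  races <- sort(unique(cohort$race))
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train_rows <- cohort[folds != f, , drop = FALSE]
    test_rows <- cohort[folds == f, , drop = FALSE]
    risk <- numeric(nrow(test_rows))
    if (strategy == "pooled") {
      fit <- fit_fold_model_(train_rows, features, config,
                             child_seed_(config$seed, f))
      risk <- unname(predict_risk(fit$model,
                                  apply_preprocessor(fit$preprocessor, test_rows)))
    } else {
      for (r in races) {
        tr <- train_rows[train_rows$race == r, , drop = FALSE]
        if (nrow(tr) == 0) stop("race stratum absent from training fold: ", r)
        te_idx <- which(test_rows$race == r)
        fit <- fit_fold_model_(tr, features, config,
                               child_seed_(config$seed, f * 10L + match(r, races)))
        if (length(te_idx) > 0) {
          risk[te_idx] <- unname(predict_risk(
            fit$model, apply_preprocessor(fit$preprocessor,
                                          test_rows[te_idx, , drop = FALSE])))
        }
      }
    }
    preds[[f]] <- data.frame(
      id = test_rows$id, race = test_rows$race,
      outcome = as.integer(test_rows$progression), fold = f,
      strategy = strategy, variant = variant, risk = risk,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, preds)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Biomarker-augmented model variant
#'
#' Trains the 18-feature variant (clinical features plus TNFR1, TNFR2 and
#' KIM-1) on the biomarker sub-cohort only. Rows lacking any biomarker are
#' an error: biomarker values are never imputed, and evaluation is
#' confined to the subset in which they were measured.
#'
#' @param cohort_subset Patient rows all carrying the three biomarkers.
#' @inheritParams run_strategy
#' @return Out-of-fold predictions (as [run_strategy()]) with
#'   `variant = "biomarker"`.
#' @export
run_biomarker_variant <- function(cohort_subset,
                                  strategy = c("pooled", "modular"),
                                  config = mlp_config(), k = 5) {
  if (anyNA(cohort_subset[, c("tnfr1", "tnfr2", "kim1")])) {
    stop("biomarkers missing for some rows; biomarker values are never imputed")
  }
  run_strategy(cohort_subset, strategy = match.arg(strategy), config = config,
               k = k, features = biomarker_features(), variant = "biomarker")
}

#' Write / read the out-of-fold predictions CSV
#'
#' Columns: `id, race, outcome, fold, strategy, variant, risk`.
#'
#' @param predictions Out-of-fold prediction data frame (possibly several
#'   strategies stacked).
#' @param path File path.
#' @export
write_predictions <- function(predictions, path) {
  write.csv(predictions, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
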