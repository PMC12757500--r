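# Pipeline orchestration: simulate -> preprocess/train (per strategy) ->
# evaluate -> decision curves, with persisted CSV/JSON artifacts and a
# run report whose every number is recomputable from the predictions CSV.

#' Default pipeline configuration
#'
#' Bundles the generator, model and evaluation blocks with a global seed
#' that propagates to every stochastic stage. The evaluation block fixes
#' the 30% operating threshold, 10 equal-frequency calibration bins and
#' the 5-50% decision-curve grid.
#'
#' @param seed Global seed (default 42), pushed into the generator and
#'   model blocks.
#' @param n_total Cohort size passed to [generator_config()].
#' @param strategies Strategies to run (default pooled and modular).
#' @param ... Overrides for [generator_config()].
#' @return A named list with blocks `generator`, `model`, `evaluation`,
#'   plus `strategies` and `seed`.
#' @export
default_pipeline_config <- function(seed = 42, n_total = 7500,
                                    strategies = c("pooled", "modular"), ...) {
  list(
    generator = generator_config(n_total = n_total, seed = seed, ...),
    model = mlp_config(seed = seed),
    evaluation = list(threshold = 0.30, n_bins = 10,
                      dca_grid = seq(0.05, 0.50, by = 0.01)),
    strategies = strategies,
    seed = as.integer(seed)
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads a structured config file whose top-level blocks mirror
#' [default_pipeline_config()]; omitted fields fall back to the package
#' defaults, and `generator`/`model` blocks are validated by their
#' constructors. An unknown top-level key is an error naming the key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param seed Optional seed overriding the file's value.
#' @return A validated pipeline configuration list.
#' @export
load_pipeline_config <- function(path, seed = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("generator", "model", "evaluation", "strategies", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) stop("unknown configuration key(s): ",
                            paste(bad, collapse = ", "))
  seed <- as.integer(seed %||% raw$seed %||% 42)
  cfg <- default_pipeline_config(seed = seed)
  if (!is.null(raw$generator)) {
    gen_args <- raw$generator
    gen_args$seed <- gen_args$seed %||% seed
    cfg$generator <- do.call(generator_config, gen_args)
  }
  if (!is.null(raw$model)) {
    mod_args <- raw$model
    mod_args$seed <- mod_args$seed %||% seed
    cfg$model <- do.call(mlp_config, mod_args)
  }
  if (!is.null(raw$evaluation)) cfg$evaluation <- modifyList(cfg$evaluation, raw$evaluation)
  if (!is.null(raw$strategies)) cfg$strategies <- raw$strategies
  cfg
}

validate_pipeline_config_ <- function(config) {
  for (block in c("generator", "model", "evaluation")) {
    if (is.null(config[[block]])) {
      stop("configuration is missing the '", block, "' block")
    }
  }
  stopifnot(inherits(config$generator, "ckd_generator_config"),
            inherits(config$model, "ckd_mlp_config"))
  invisible(config)
}

# Table-2-shaped block of discrimination and classification metrics for
# one strategy's out-of-fold predictions
strategy_metrics_ <- function(preds, threshold, n_bins) {
  races <- sort(unique(preds$race))
  per_race <- lapply(races, function(r) {
    d <- preds[preds$race == r, ]
    comp <- delong_components_(d$risk, d$outcome)
    rates <- classification_rates(
      confusion_at_threshold(d$risk, d$outcome, threshold, group = r))
    ci <- comp$auc + c(-1, 1) * qnorm(0.975) * sqrt(comp$var)
    list(rates = rates, auc = comp$auc, auc_ci = ci,
         calibration = calibration_report(d, n_bins = n_bins))
  })
  names(per_race) <- races
  rates_tab <- do.call(rbind, lapply(per_race, `[[`, "rates"))
  rates_tab$auc <- vapply(per_race, `[[`, numeric(1), "auc")
  rates_tab$auc_lo <- vapply(per_race, function(z) z$auc_ci[1], numeric(1))
  rates_tab$auc_hi <- vapply(per_race, function(z) z$auc_ci[2], numeric(1))
  gaps <- if (all(c("Black", "White") %in% races)) {
    fairness_gaps(per_race$Black$rates, per_race$White$rates,
                  per_race$Black$auc, per_race$White$auc)
  }
  delong <- if (all(c("Black", "White") %in% races)) {
    b <- preds[preds$race == "Black", ]; w <- preds[preds$race == "White", ]
    delong_auc_difference(b$risk, b$outcome, w$risk, w$outcome)
  }
  list(
    overall_auc = auc(preds$risk, preds$outcome),
    overall_rates = classification_rates(
      confusion_at_threshold(preds$risk, preds$outcome, threshold,
                             group = "overall")),
    rates_by_race = rates_tab,
    calibration_by_race = lapply(per_race, `[[`, "calibration"),
    gaps = gaps,
    delong_race_difference = delong
  )
}

summarize_cohort_ <- function(cohort) {
  do.call(rbind, lapply(split(as.data.frame(cohort), cohort$race), function(d) {
    data.frame(
      race = d$race[1], n = nrow(d),
      progression_rate = mean(d$progression),
      egfr_mean = mean(d$egfr_baseline),
      uacr_median = median(d$uacr),
      diabetes_prevalence = mean(d$diabetes),
      age_mean = mean(d$age),
      stringsAsFactors = FALSE
    )
  }))
}

#' Run the full simulation-to-audit pipeline
#'
#' Generates the cohort, trains the requested strategies under stratified
#' cross-validation, evaluates discrimination, calibration and fairness at
#' the configured operating threshold, runs decision-curve analysis, and
#' (when `output_dir` is given) persists `cohort.csv`, `predictions.csv`,
#' `metrics.json`, `dca.csv`, `reliability_bins.csv` and a Markdown
#' summary. Rerunning with the same config and seed reproduces identical
#' CSV/JSON artifacts.
#'
#' @param config A pipeline configuration (see
#'   [default_pipeline_config()], [load_pipeline_config()]).
#' @param output_dir Directory for artifacts, or `NULL` for none.
#' @return An (invisible for large runs) run-report list: `cohort_summary`,
#'   per-strategy `metrics`, `dca` table, raw `predictions`, `cohort`, and
#'   `provenance` (seed, package version).
#' @export
run_pipeline <- function(config = default_pipeline_config(), output_dir = NULL) {
  validate_pipeline_config_(config)
  cohort <- generate_cohort(config$generator)
  preds <- do.call(rbind, lapply(config$strategies, function(s) {
    run_strategy(cohort, s, config = config$model)
  }))
  ev <- config$evaluation
  metrics <- lapply(split(preds, preds$strategy), strategy_metrics_,
                    threshold = ev$threshold, n_bins = ev$n_bins)
  dca <- do.call(rbind, lapply(split(preds, preds$strategy), function(d) {
    out <- decision_curve(d$risk, d$outcome, grid = ev$dca_grid)
    out$strategy <- d$strategy[1]
    out
  }))
  rownames(dca) <- NULL
  report <- list(
    cohort_summary = summarize_cohort_(cohort),
    metrics = metrics,
    dca = dca,
    predictions = preds,
    cohort = cohort,
    provenance = list(
      seed = config$seed,
      threshold = ev$threshold,
      n_bins = ev$n_bins,
      strategies = config$strategies,
      package_version = as.character(utils::packageVersion("ckdfair"))
    )
  )
  class(report) <- "ckd_run_report"
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(output_dir, "cohort.csv"))
    write_predictions(preds, file.path(output_dir, "predictions.csv"))
    jsonlite::write_json(metrics_to_json_(metrics),
                         file.path(output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(dca, file.path(output_dir, "dca.csv"), row.names = FALSE)
    write.csv(report_bins_(metrics),
              file.path(output_dir, "reliability_bins.csv"), row.names = FALSE)
    writeLines(format_report_md_(report), file.path(output_dir, "report.md"))
  }
  report
}

metrics_to_json_ <- function(metrics) {
  lapply(metrics, function(m) {
    list(
      overall_auc = m$overall_auc,
      rates_by_race = m$rates_by_race,
      gaps = m$gaps,
      calibration_by_race = lapply(m$calibration_by_race, function(cr) {
        list(citl_pp = cr$citl_pp, ece = cr$ece, brier = cr$brier,
             slope = if (!is.null(cr$slope)) cr$slope$slope else NA,
             slope_ci = if (!is.null(cr$slope)) cr$slope$ci else NULL)
      }),
      delong_race_difference = m$delong_race_difference
    )
  })
}

report_bins_ <- function(metrics) {
  do.call(rbind, unlist(lapply(names(metrics), function(s) {
    lapply(names(metrics[[s]]$calibration_by_race), function(r) {
      b <- metrics[[s]]$calibration_by_race[[r]]$bins
      b$strategy <- s
      b$race <- r
      b
    })
  }), recursive = FALSE))
}

format_report_md_ <- function(report) {
  lines <- c("# CKD progression risk-model fairness audit", "",
             sprintf("Seed %d; operating threshold %.0f%%.",
                     report$provenance$seed, 100 * report$provenance$threshold),
             "", "## Cohort", "")
  cs <- report$cohort_summary
  lines <- c(lines, sprintf(
    "- %s: n=%d, progression %.1f%%, mean eGFR %.1f, median UACR %.0f, diabetes %.1f%%",
    cs$race, cs$n, 100 * cs$progression_rate, cs$egfr_mean, cs$uacr_median,
    100 * cs$diabetes_prevalence))
  for (s in names(report$metrics)) {
    m <- report$metrics[[s]]
    lines <- c(lines, "", sprintf("## Strategy: %s", s), "",
               sprintf("Overall out-of-fold AUC: %.3f", m$overall_auc), "")
    rt <- m$rates_by_race
    lines <- c(lines, sprintf(
      "- %s: AUC %.3f (%.3f-%.3f), TPR %.1f%%, FPR %.1f%%, PPV %s, flagged %.1f%%, CITL %+.2f pp",
      rt$group, rt$auc, rt$auc_lo, rt$auc_hi, 100 * rt$tpr, 100 * rt$fpr,
      ifelse(is.na(rt$ppv), "undefined", sprintf("%.1f%%", 100 * rt$ppv)),
      100 * rt$flag_rate,
      vapply(m$calibration_by_race[rt$group], `[[`, numeric(1), "citl_pp")))
    if (!is.null(m$gaps)) {
      lines <- c(lines, "", sprintf(
        "Black-White gaps (pp): TPR %+.1f, FPR %+.1f, PPV %s, flag rate %+.1f",
        m$gaps$tpr_gap, m$gaps$fpr_gap,
        if (is.na(m$gaps$ppv_gap)) "undefined" else sprintf("%+.1f", m$gaps$ppv_gap),
        m$gaps$flag_rate_gap))
    }
  }
  lines
}

#' Render calibration and decision-curve figures
#'
#' Writes one reliability diagram per race (both strategies against the
#' diagonal) and one decision-curve plot (model curves with treat-all and
#' treat-none references), each as PNG plus the exact data behind it as
#' CSV.
#'
#' @param report A `ckd_run_report` from [run_pipeline()].
#' @param output_dir Directory for the image and CSV files.
#' @return Invisibly, the written file paths.
#' @export
render_plots <- function(report, output_dir) {
  stopifnot(inherits(report, "ckd_run_report"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  bins <- report_bins_(report$metrics)
  paths <- character(0)
  for (r in unique(bins$race)) {
    d <- bins[bins$race == r, ]
    p <- ggplot2::ggplot(d, ggplot2::aes(x = mean_pred, y = obs_rate,
                                         color = strategy, shape = strategy)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           color = "grey50") +
      ggplot2::geom_point(size = 2.5) +
      ggplot2::geom_line() +
      ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(x = "Predicted 5-year risk", y = "Observed event rate",
                    title = paste("Calibration,", r, "patients")) +
      ggplot2::theme_minimal()
    png_path <- file.path(output_dir, paste0("calibration_", tolower(r), ".png"))
    ggplot2::ggsave(png_path, p, width = 5, height = 5, dpi = 150)
    csv_path <- sub("\\.png$", ".csv", png_path)
    write.csv(d, csv_path, row.names = FALSE)
    paths <- c(paths, png_path, csv_path)
  }
  dca <- report$dca
  ref <- dca[dca$strategy == dca$strategy[1],
             c("threshold", "nb_treat_all", "nb_treat_none")]
  p <- ggplot2::ggplot(dca, ggplot2::aes(x = threshold, y = nb_model,
                                         color = strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_line(data = ref,
                       mapping = ggplot2::aes(x = threshold, y = nb_treat_all),
                       color = "red", inherit.aes = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(-0.05, max(dca$nb_model, na.rm = TRUE) + 0.02)) +
    ggplot2::labs(x = "Risk threshold", y = "Net benefit (TP equivalents/patient)",
                  title = "Decision curve analysis") +
    ggplot2::theme_minimal()
  png_path <- file.path(output_dir, "decision_curve.png")
  ggplot2::ggsave(png_path, p, width = 6, height = 4.5, dpi = 150)
  write.csv(dca, file.path(output_dir, "decision_curve.csv"), row.names = FALSE)
  paths <- c(paths, png_path, file.path(output_dir, "decision_curve.csv"))
  invisible(paths)
}
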