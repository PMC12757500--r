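---
title: "Auditing pooled vs race-specific CKD progression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing pooled vs race-specific CKD progression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ckdfair` implements a controlled experiment on algorithmic fairness in
clinical risk prediction: does a race-blind ("pooled") neural-network
model of five-year chronic kidney disease (CKD) progression miscalibrate
by race, and does a race-stratified ("modular") design repair that
miscalibration without losing discrimination? Because individual-level
records from the population studies this experiment emulates (NHANES,
CRIC, UK Biobank) are access-restricted, the package's first-class
component is a cohort *simulator* whose defaults encode the published
summary characteristics of such a pooled stage 1–4 CKD population; the
models and the audit then run on simulated patients exactly as they
would on real ones.

This vignette documents the model, its assumptions, the tunable
parameters, and the design decisions taken where the protocol left
genuine latitude.

## 1. The synthetic cohort

### Covariates

Each race stratum is drawn from a 15-dimensional latent Gaussian with
the correlation matrix `default_correlation_matrix()` (unit diagonal,
positive semi-definite; clinically familiar structure such as
eGFR–albuminuria −0.35, SBP–DBP 0.60, HbA1c–glucose 0.60). Latent
coordinates map to the clinical scale by:

* location/scale shifts for continuous labs (per-race means and SDs in
  `default_covariates_`), with age floored at 18 and baseline eGFR
  clamped to [15, 120] ml/min/1.73 m² (stage 1–4 by construction);
* exponentiation for UACR, giving a log-normal with the configured
  per-race median (120 mg/g Black, 60 mg/g White; log-SD 1.3);
* thresholding of the comorbidity liabilities at the normal quantile of
  the configured prevalence (diabetes 45%/40%, hypertension 75%/70%,
  CVD 22%/18% — the latter two are not published for this population
  and are documented assumptions).

Race counts are exact (largest-remainder stratified allocation), not
sampled. Serum creatinine is back-computed from the drawn eGFR by the
closed-form inverse of the CKD-EPI 2021 equation, so the recorded labs
are internally consistent. Sex is Bernoulli(0.5), independent of the
latent field.

### Outcome model

Progression is assigned probabilistically *first* and the eGFR
trajectory constructed *second* (the two-layer design makes the
published marginal rates easy to pin; generating slopes first and
letting rates emerge would not). The per-race linear predictor is a
logistic model on the latent standardized covariates plus an unobserved
standard-normal *frailty* term (weight 0.85) representing risk factors
outside the 15-feature panel; the plasma biomarkers load on the
standardized total risk, so frailty is exactly the information a
biomarker-augmented model can add. Intercepts are solved by bracketed
bisection (`calibrate_intercept()`, achieved marginal within 1e-6) so
the marginal five-year progression rates hit 28% (Black) and 20%
(White). The overall rate is therefore emergent (≈ 23.2%); the two
published per-race counts are treated as the binding targets because
they are mutually consistent while the published overall count is not.

The default coefficient vectors differ by race — heavier albuminuria
and blood-pressure weights in the Black stratum, heavier
age/glycemia weights in the White stratum — and are arranged so that
most of the 8-point marginal gap is *conditional on covariates* rather
than explained by covariate shift. This is the substantive premise of
the experiment: a Black patient carries higher risk than a
covariate-matched White patient (unmeasured genetic, socio-environmental
and access factors), which is precisely what a race-blind model cannot
represent and why it under-predicts for the Black stratum. These
magnitudes were calibrated once, as the generator's definition of the
study conditions, so that the pooled pipeline's out-of-fold AUC sits
near 0.79 and the biomarker variant's AUC gain near +0.02; they are not
re-tuned per run.

### Trajectories and the composite endpoint

`ascertain_progression()` operationalizes the composite endpoint as the
union of three clauses:

1. *sustained ≥ 40% drop*: some annual value falls to ≤ 60% of baseline
   and **every later value stays there** (the protocol says only
   "sustained"; persistence through year 5 once reached is the chosen
   reading);
2. *confirmed decline ≥ 5 ml/min/1.73 m²/yr*: the decline reaches 5 in
   **two consecutive** year-to-year intervals (confirmation =
   repetition; the confirmation window is otherwise undefined);
3. kidney failure (dialysis/transplant listing) in years 1–5.

Trajectories are linear declines (progressors −7 ± 1.5, non-progressors
−1 ± 1 ml/min/1.73 m²/yr) plus measurement noise (SD 1.5), floored at
zero, with a 6%/yr kidney-failure hazard among progressors. Noise draws
are rejected until the rule re-derives the assigned label (a noise-free
fallback qualifies by construction), so the label round-trip
`ascertain_progression(trajectory) == progression` holds for every
patient — a property the test suite checks cohort-wide.

### What the simulator does and does not emulate

It matches the published *summary* characteristics (race mix, eGFR
means, UACR medians, diabetes prevalences, event rates) and a plausible
correlation structure; it does not attempt to match real microdata, has
no longitudinal covariates other than eGFR, no competing-risk death, no
informative missingness (covariates are complete by construction; the
preprocessor's imputation path is exercised by unit tests), and a
biomarker sub-cohort (n = 1,200, labeled `EHR_A_like`) selected at
random rather than by care pattern. Passing end-to-end tests therefore
demonstrates that the *pipeline* behaves as the protocol describes under
these conditions — not that the models would calibrate equally well on
real EHR data.

## 2. Harmonization

`fit_preprocessor()` / `apply_preprocessor()` apply, in order:
winsorization to fixed physiologic bounds (e.g. UACR 1–10,000 mg/g, SBP
70–250 mmHg; the protocol names no bounds, so these are configurable
package defaults), natural-log UACR ("logarithmic scale" is read as the
natural log), mean imputation, and centering/scaling. All statistics are
computed per **source cohort × training fold** — "within each cohort"
scaling scoped to the training portion — and the state is a pure
function of the training rows, which the suite verifies by mutating
test rows and asserting bit-identical state. Binary indicators pass
through unscaled with missing comorbidities coded absent.

The 15-feature panel is: age, sex, baseline eGFR, log-UACR, SBP, DBP,
diabetes, hypertension, CVD, HbA1c, glucose, LDL, HDL, triglycerides,
hemoglobin. The protocol lists the categories but not the final list;
hemoglobin is retained (anemia is an established progression marker)
and total cholesterol is carried in the schema but not modeled, since
LDL/HDL/triglycerides already span the lipid signal. Race is never a
feature. The biomarker variant appends TNFR1, TNFR2 and KIM-1 (18
features) and refuses rows with missing biomarkers — they are never
imputed.

## 3. Training protocol

| parameter | default | note |
|---|---|---|
| hidden layers | 64, 32 (ReLU) | fixed; no per-fold architecture search |
| output | sigmoid probability | |
| loss | binary cross-entropy, weight 3 on progressors | plus `0.001·Σw²` L2 on weights |
| optimizer | Adam, lr 0.001, β = (0.9, 0.999), ε = 1e-8 | canonical constants |
| batch size | 32, reshuffled per epoch | |
| epochs | ≤ 100, patience 10 on validation loss | best-epoch weights restored |
| validation carve-out | 20% of the training portion, outcome-stratified | protocol gives no fraction |
| oversampling | duplication ×2 of the minority class | "modest", unspecified; configurable |
| seed | 42 | drives init, shuffling, folds, carve-outs |

Folds are stratified jointly on outcome × race so each fold carries a
comparable race composition and event rate. Within each training fold
the order is: fit preprocessor → carve validation subset → duplicate
minority-class rows in the remaining 80% → train → recalibrate.
Validation loss is monitored unweighted, matching the convention of the
common deep-learning frameworks in which class weights shape only the
training objective.

### Recalibration (a package design decision)

Class weight 3 combined with duplication oversampling ×2 multiplies the
effective odds of the positive class by roughly six, so the raw sigmoid
outputs estimate a tilted posterior `q` with
`logit(q) ≈ logit(p) + log 6` — far from the probability scale on which
calibration-in-the-large is assessed. Each fold model is therefore
recalibrated inside its own training fold, in two steps
(`recalibrate_model()`):

1. a **calibration slope** is estimated by logistic regression of the
   validation-carve-out outcomes on the raw prediction logits (the
   carve-out is untouched by gradient updates, so it reflects
   out-of-sample over- or under-confidence);
2. a **constant logit shift** is then solved by the same bisection used
   for generator intercepts so the slope-adjusted mean predicted risk
   over the full, un-oversampled, unweighted training portion equals
   that portion's event rate.

The correction is race-blind for the pooled strategy and within-race
for the modular strategy, and never sees test-fold rows. With it, the
modular model's per-race calibration-in-the-large sits within a few
hundredths of a percentage point, while the pooled model's per-race
miscalibration (under-prediction for the Black stratum, over-prediction
for the White) is exposed as a structural property of race-blind
pooling rather than an artifact of the weighted loss.

## 4. Evaluation conventions

* All metrics use out-of-fold predictions only; `run_strategy()` emits
  exactly one prediction per patient, made by a model whose training
  folds excluded that patient.
* Flagging is boundary-inclusive (`score ≥ p_t`) everywhere, including
  decision curves. The operating threshold is 30% five-year risk.
* Reliability bins are equal-frequency (deciles by default) with stable
  tie-breaking on (score, id); bin counts differ by at most one.
* Calibration-in-the-large, ECE and Brier are computed per fold and
  averaged; the calibration slope and AUC are computed on the pooled
  out-of-fold predictions, where the larger sample stabilizes the
  logistic recalibration and the rank statistic.
* PPV with an empty flagged set is reported as an explicit undefined
  (`NA`), never as 0; gaps involving it propagate as `NA`.
* The DeLong AUC variance uses the structural-components estimator;
  the Black/White comparison is an independent two-sample z-test since
  the groups are disjoint. Chi-square tests are Pearson without
  continuity correction. No multiple-testing correction is applied.
* Decision curves run over 5–50% in 1-point steps (the grid step is a
  package choice) on the combined cohort; per-race curves are available
  by subsetting the predictions.

## 5. Numerical choices and determinism

Intercept searches use `uniroot` on ±20 logits (tolerance 1e-10); the
calibration-slope GLM uses IWLS with convergence tolerance 1e-8;
cross-entropy is clipped at 1e-7; recalibration logits at 1e-12.
Everything downstream of a `(config, seed)` pair is deterministic —
cohort, folds, carve-outs, initialization, batch order — and the
pipeline writes byte-identical CSV/JSON artifacts on rerun; exact
floating-point reproducibility additionally assumes single-threaded
BLAS. Seeds for fold models are derived from the global seed by a
bounded integer map so they remain valid 32-bit values.

Two protocol variants were deliberately not implemented: the hybrid
network with a race-specific final layer (reported equivalent to fully
separate models; the strategy argument leaves room for it) and any
fairness *mitigation* (reweighting, per-group thresholds, adversarial
debiasing) — the package audits, it does not repair.

## 6. Problem sizes in the test suite

The suite exercises the full default configuration (n = 7,500, both
strategies, 5 folds) once per session and reuses the cached run across
end-to-end checks; property tests run on smaller cohorts (500–1,500
patients) with a reduced epoch budget, sizes chosen so each property is
measured well inside its Monte-Carlo tolerance. The null-signal check
permutes labels on a 1,000-patient cohort and expects chance-level
out-of-fold AUC; the homogeneity check gives both races identical
generating processes and expects pooled and modular per-race AUCs to
agree within sampling error; slope recovery uses 20,000
Bernoulli(score) draws.

## 7. Known limitations

* The simulator's conditional race gap is a modeling premise, not an
  estimate; its magnitude (and hence the pooled model's per-race
  calibration error, about −1 pp for the Black stratum under the
  defaults) is smaller than what a real EHR population might show.
* Calibration-in-the-large of the modular model benefits from the
  recalibration step by construction; the informative comparison is the
  *pooled* model's failure under the identical correction.
* The MLP is trained single-threaded in base R; it is intentionally
  small, and no hyperparameter search is performed beyond the fixed
  protocol values.
* "Other" race categories are supported by the data model but excluded
  from the default generator; modular training requires every modeled
  race stratum to be present in every training fold.
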