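#' Coefficients of the race-free CKD-EPI 2021 creatinine equation
#'
#' Returns the published constants of the 2021 CKD-EPI creatinine equation
#' (the race-free refit): overall scale 142, sex-specific creatinine knot
#' `kappa` (0.7 female / 0.9 male, mg/dL), sex-specific low-creatinine
#' exponent `alpha` (-0.241 / -0.302), high-creatinine exponent -1.200,
#' per-year age factor 0.9938 and female multiplier 1.012. Kept as a
#' parameter object rather than constants inside [ckd_epi_2021()] so
#' alternative creatinine equations can be swapped in.
#'
#' @return A list with elements `scale`, `kappa`, `alpha`,
#'   `scr_exponent_high`, `age_factor`, `sex_factor`.
#' @export
ckd_epi_params <- function() {
  list(
    scale = 142,
    kappa = c(female = 0.7, male = 0.9),
    alpha = c(female = -0.241, male = -0.302),
    scr_exponent_high = -1.200,
    age_factor = 0.9938,
    sex_factor = 1.012
  )
}

normalize_sex_ <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female")] <- "female"
  s[s %in% c("m", "male")] <- "male"
  bad <- !s %in% c("female", "male")
  if (any(bad)) {
    stop("unrecognized sex value(s): ", paste(unique(sex[bad]), collapse = ", "))
  }
  s
}

#' Estimated GFR from serum creatinine (CKD-EPI 2021, race-free)
#'
#' Computes eGFR (ml/min/1.73 m\eqn{^2}) as
#' \deqn{142 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
#'       \max(S_{cr}/\kappa, 1)^{-1.200} \cdot 0.9938^{age}
#'       \cdot 1.012\,[\mathrm{if\ female}]}
#' with sex-specific \eqn{\kappa} and \eqn{\alpha}. Strictly decreasing in
#' creatinine and in age. Vectorized over all arguments.
#'
#' @param scr Serum creatinine, mg/dL; must be positive.
#' @param age Age in years; adults (>= 18) expected.
#' @param sex `"female"`/`"male"` (or `"F"`/`"M"`), recycled as needed.
#' @param params Equation constants, see [ckd_epi_params()].
#' @return eGFR in ml/min/1.73 m\eqn{^2}.
#' @examples
#' ckd_epi_2021(0.9, 60, "male")   # ~97.8
#' ckd_epi_2021(0.7, 40, "female") # ~112.1
#' @export
ckd_epi_2021 <- function(scr, age, sex, params = ckd_epi_params()) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("serum creatinine must be positive")
  }
  if (any(age < 18)) stop("ckd_epi_2021 is defined for adults (age >= 18)")
  sex <- normalize_sex_(sex)
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  r <- scr / params$kappa[sex]
  unname(
    params$scale *
      pmin(r, 1)^params$alpha[sex] *
      pmax(r, 1)^params$scr_exponent_high *
      params$age_factor^age *
      ifelse(sex == "female", params$sex_factor, 1)
  )
}

#' Serum creatinine consistent with a target eGFR
#'
#' Closed-form inverse of [ckd_epi_2021()] at fixed age and sex; used by the
#' cohort generator, which draws baseline eGFR directly and back-computes the
#' creatinine that would have produced it.
#'
#' @inheritParams ckd_epi_2021
#' @param egfr Target eGFR, ml/min/1.73 m\eqn{^2}; must be positive.
#' @return Serum creatinine in mg/dL.
#' @export
invert_ckd_epi_2021 <- function(egfr, age, sex, params = ckd_epi_params()) {
  if (any(egfr <= 0)) stop("egfr must be positive")
  sex <- normalize_sex_(sex)
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  base <- params$scale * params$age_factor^age *
    ifelse(sex == "female", params$sex_factor, 1)
  a <- egfr / base # = g(r), g decreasing, g(1) = 1
  r <- ifelse(a <= 1, a^(1 / params$scr_exponent_high), a^(1 / params$alpha[sex]))
  unname(r * params$kappa[sex])
}
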