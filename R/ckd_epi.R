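#' CKD-EPI 2009 creatinine equation
#'
#' Estimated glomerular filtration rate from serum creatinine, age and sex,
#' using the 2009 CKD-EPI creatinine equation:
#' \deqn{141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
#'       \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot
#'       1.018\,[\mathrm{if\ female}]}
#' with \eqn{\kappa = 0.7} (female) / 0.9 (male) and
#' \eqn{\alpha = -0.329} (female) / \eqn{-0.411} (male). The race coefficient
#' is deliberately omitted: it is not derivable from the fields this package
#' works with and is irrelevant to the model mechanisms under test.
#'
#' @param creatinine Serum creatinine in mg/dL; must be positive.
#' @param age Age in years; must be non-negative.
#' @param sex Character vector, `"female"` or `"male"`.
#' @return eGFR in ml/min per 1.73 m^2. Vectorised over all arguments.
#' @examples
#' ckd_epi_egfr(0.7, 40, "female")  # ~108.4
#' ckd_epi_egfr(1.2, 50, "male")    # ~70.1
#' @export
ckd_epi_egfr <- function(creatinine, age, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    abort_input("creatinine must be positive", "adpkdval_domain_error")
  }
  if (any(!is.finite(age)) || any(age < 0)) {
    abort_input("age must be non-negative", "adpkdval_domain_error")
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- creatinine / kappa
  141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1)
}

#' Invert the CKD-EPI equation for serum creatinine
#'
#' Solves the 2009 CKD-EPI creatinine equation for serum creatinine given a
#' target eGFR. Used by the synthetic cohort generator, which parameterises
#' eGFR directly and back-derives a consistent creatinine; this inverse has
#' no clinical use and is synthetic-only.
#'
#' @param egfr Target eGFR in ml/min per 1.73 m^2; must be positive.
#' @inheritParams ckd_epi_egfr
#' @return Serum creatinine in mg/dL such that [ckd_epi_egfr()] returns
#'   `egfr`.
#' @export
ckd_epi_creatinine <- function(egfr, age, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    abort_input("egfr must be positive", "adpkdval_domain_error")
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  base <- 141 * 0.993^age * ifelse(female, 1.018, 1)
  c_ratio <- egfr / base  # = min(r,1)^alpha * max(r,1)^-1.209, decreasing in r
  # c_ratio > 1 corresponds to creatinine below kappa (the alpha branch).
  ifelse(c_ratio > 1,
         kappa * c_ratio^(1 / alpha),
         kappa * c_ratio^(1 / -1.209))
}

match_sex <- function(sex) {
  sex <- as.character(sex)
  ok <- sex %in% c("female", "male")
  if (any(!ok)) {
    abort_input("sex must be 'female' or 'male'", "adpkdval_domain_error")
  }
  sex
}
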