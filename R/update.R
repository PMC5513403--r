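#' Partially update a frozen coefficient set with new kidney-volume data
#'
#' Re-estimates only the HtTKV regression coefficient (and, optionally, its
#' interaction with years of follow-up) against a validation cohort, holding
#' every other regression coefficient — including the intercept — fixed at
#' its external value. The frozen part of the linear predictor enters the
#' mixed-model likelihood as an offset; the variance components are always
#' re-estimated (only regression coefficients are frozen).
#'
#' Two update modes:
#' \describe{
#'   \item{`model1_two_tkv`}{adds each patient's second HtTKV measurement
#'     (the earliest follow-up visit with a non-missing value, typically
#'     6-12 months after baseline) as an additional `log2_httkv_second`
#'     term with a freshly estimated coefficient; the baseline HtTKV terms
#'     stay frozen. With `replace_baseline = TRUE` the second measurement
#'     instead replaces the baseline value as the model's HtTKV covariate.}
#'   \item{`model2_time_varying`}{redefines the model's HtTKV covariate as
#'     the time-varying log2 HtTKV observed at each visit and refits its
#'     main coefficient. Without `with_interaction` the time interaction
#'     coefficient keeps its frozen value (applied to the redefined
#'     covariate); with it, the interaction coefficient is refit too.}
#' }
#' Visits (model 2) or patients (model 1) lacking the required HtTKV value
#' are dropped from the refit; impute first to use them all.
#'
#' @param coeffs Frozen `egfr_model_coefficients` in `continuous_httkv`
#'   mode.
#' @param cohort Validation [long_cohort()].
#' @param update_mode `"model1_two_tkv"` or `"model2_time_varying"`.
#' @param with_interaction Also refit the HtTKV-by-years interaction
#'   coefficient.
#' @param replace_baseline Model-1 variant: replace the baseline HtTKV
#'   covariate instead of adding a second term.
#' @param reml Use REML for the refit (default ML).
#' @return An `egfr_model_coefficients` object whose frozen coefficients are
#'   bit-identical to the input and whose refit terms, variance components
#'   and `httkv_source` reflect the update; attributes `loglik`, `n_obs`,
#'   `n_params` (refit coefficients plus the two variance components),
#'   `refit_terms`, `fit_method`.
#' @export
partial_update <- function(coeffs, cohort,
                           update_mode = c("model1_two_tkv",
                                           "model2_time_varying"),
                           with_interaction = FALSE,
                           replace_baseline = FALSE,
                           reml = FALSE) {
  update_mode <- match.arg(update_mode)
  stopifnot(inherits(coeffs, "egfr_model_coefficients"),
            inherits(cohort, "adpkd_long_cohort"))
  if (coeffs$mode != "continuous_httkv") {
    abort_input("partial updating is only supported in continuous_httkv mode",
                class = "adpkdval_unsupported_mode")
  }

  if (update_mode == "model1_two_tkv" && !replace_baseline) {
    refit_terms <- c("log2_httkv_second",
                     if (with_interaction) "t_log2_httkv_second")
    new_source <- "baseline"
  } else {
    refit_terms <- c("log2_httkv", if (with_interaction) "t_log2_httkv")
    new_source <- if (update_mode == "model1_two_tkv")
      "second_measurement" else "time_varying"
  }
  frozen_terms <- setdiff(names(coeffs$beta), refit_terms)

  work <- coeffs
  work$httkv_source <- new_source
  add <- setdiff(refit_terms, names(work$beta))
  work$beta <- c(work$beta, setNames(numeric(length(add)), add))
  df <- build_visit_frame(work, cohort)
  if (update_mode == "model1_two_tkv" &&
      (nrow(df) == 0 || all(is.na(df$log2_httkv_second %||% NA)))) {
    abort_input("no patient has a second (follow-up) HtTKV measurement")
  }
  if (nrow(df) < 2) {
    abort_input("too few usable visits for the update; impute HtTKV first")
  }

  off <- drop(design_matrix_terms(df, frozen_terms) %*%
                coeffs$beta[frozen_terms])
  Z <- design_matrix_terms(df, refit_terms)
  dat <- cbind(as.data.frame(Z),
               data.frame(egfr_obs = df$egfr_obs, t_years = df$t_years,
                          patient_id = df$patient_id, .offset = off))
  fml <- stats::as.formula(paste(
    "egfr_obs ~ 0 +", paste(refit_terms, collapse = " + "),
    "+ (0 + t_years | patient_id)"))
  fit <- lme4::lmer(fml, data = dat, REML = reml, offset = dat$.offset,
                    control = lme4::lmerControl(calc.derivs = FALSE))

  new_beta <- coeffs$beta
  new_beta[refit_terms] <- lme4::fixef(fit)[refit_terms]
  vc <- lme4::VarCorr(fit)
  out <- model_coefficients(coeffs$mode, new_beta,
                            vc$patient_id["t_years", "t_years"],
                            stats::sigma(fit)^2,
                            httkv_source = new_source)
  ll <- logLik(fit)
  attr(out, "loglik") <- as.numeric(ll)
  attr(out, "n_params") <- length(refit_terms) + 2L
  attr(out, "n_obs") <- nrow(dat)
  attr(out, "refit_terms") <- refit_terms
  attr(out, "fit_method") <- if (reml) "REML" else "ML"
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
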