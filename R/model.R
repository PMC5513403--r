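#' Linear mixed-model coefficient set for eGFR prediction
#'
#' Container for the fixed effects and variance components of the
#' Mayo-form eGFR model
#' \deqn{eGFR_{it} = x_{it}\beta + b_i t + \varepsilon_{it},\qquad
#'       b_i \sim N(0, \sigma^2_b),\ \varepsilon \sim N(0, \sigma^2)}
#' where the fixed-effect design contains baseline predictors (log2 HtTKV or
#' risk-class indicators, age, sex, baseline eGFR), linear time, and the
#' interaction of time with every baseline predictor. The random effect is a
#' subject-specific slope on years of follow-up.
#'
#' @param mode `"continuous_httkv"` (log2 HtTKV predictor) or `"risk_class"`
#'   (indicator terms for classes 1B-1E, 1A reference).
#' @param beta Named numeric vector covering exactly the term set of `mode`
#'   (see [model_terms()]), optionally extended by the second-measurement
#'   HtTKV terms created by [partial_update()].
#' @param var_random_slope Variance of the subject-specific slope,
#'   (ml/min/1.73m^2/yr)^2; non-negative.
#' @param var_residual Residual variance, (ml/min/1.73m^2)^2; non-negative.
#' @param httkv_source Which HtTKV measurement feeds the `log2_httkv` term
#'   when predicting: `"baseline"` (default), `"second_measurement"`, or
#'   `"time_varying"`. Set by [partial_update()].
#' @return An object of class `egfr_model_coefficients`.
#' @seealso [fit_development_model()], [predict_egfr()], [partial_update()]
#' @export
model_coefficients <- function(mode = c("continuous_httkv", "risk_class"),
                               beta, var_random_slope, var_residual,
                               httkv_source = c("baseline",
                                                "second_measurement",
                                                "time_varying")) {
  mode <- match.arg(mode)
  httkv_source <- match.arg(httkv_source)
  assert_that(is.numeric(beta) && !is.null(names(beta)) &&
                all(nzchar(names(beta))),
              "beta must be a fully named numeric vector")
  assert_that(is_scalar_number(var_random_slope) && var_random_slope >= 0,
              "var_random_slope must be a non-negative number")
  assert_that(is_scalar_number(var_residual) && var_residual >= 0,
              "var_residual must be a non-negative number")
  required <- model_terms(mode)
  extra <- setdiff(names(beta), required)
  allowed_extra <- c("log2_httkv_second", "t_log2_httkv_second")
  if (length(setdiff(required, names(beta))) > 0) {
    abort_input(paste0("beta is missing terms: ",
                       paste(setdiff(required, names(beta)), collapse = ", ")))
  }
  if (length(setdiff(extra, allowed_extra)) > 0) {
    abort_input(paste0("unknown beta terms: ",
                       paste(setdiff(extra, allowed_extra), collapse = ", ")))
  }
  structure(list(mode = mode,
                 beta = beta[c(required, intersect(allowed_extra, names(beta)))],
                 var_random_slope = var_random_slope,
                 var_residual = var_residual,
                 httkv_source = httkv_source),
            class = "egfr_model_coefficients")
}

#' Fixed-effect term names for a model mode
#'
#' @inheritParams model_coefficients
#' @return Character vector of term names, in design order. Interaction terms
#'   with years of follow-up carry a `t_` prefix.
#' @export
model_terms <- function(mode = c("continuous_httkv", "risk_class")) {
  mode <- match.arg(mode)
  base <- if (mode == "continuous_httkv") "log2_httkv" else
    paste0("class_1", c("B", "C", "D", "E"))
  baseline_terms <- c(base, "age0", "sex", "egfr0")
  c("intercept", baseline_terms, "t", paste0("t_", baseline_terms))
}

#' @export
print.egfr_model_coefficients <- function(x, ...) {
  cat("eGFR mixed-model coefficients (", x$mode, " mode)\n", sep = "")
  cat("  HtTKV source: ", x$httkv_source, "\n", sep = "")
  print(round(x$beta, 6))
  cat(sprintf("  var(random slope) = %.4f  var(residual) = %.4f\n",
              x$var_random_slope, x$var_residual))
  ll <- attr(x, "loglik")
  if (!is.null(ll)) {
    cat(sprintf("  logLik = %.2f on %d obs (%s)\n", ll,
                attr(x, "n_obs"), attr(x, "fit_method")))
  }
  invisible(x)
}

# Value of one design term on a visit-level frame. The frame must carry
# log2_httkv (whatever measurement the caller chose to feed the HtTKV term),
# age0, sex_num (female = 1, male = 0), egfr0, t_years, risk_class0 in class
# mode, and log2_httkv_second when that term is requested.
term_column <- function(term, df) {
  if (term == "intercept") return(rep(1, nrow(df)))
  if (term == "t") return(df$t_years)
  if (startsWith(term, "t_")) {
    return(df$t_years * term_column(sub("^t_", "", term), df))
  }
  switch(term,
    log2_httkv = df$log2_httkv,
    log2_httkv_second = df$log2_httkv_second,
    age0 = df$age0,
    sex = df$sex_num,
    egfr0 = df$egfr0,
    class_1B = as.numeric(df$risk_class0 == "1B"),
    class_1C = as.numeric(df$risk_class0 == "1C"),
    class_1D = as.numeric(df$risk_class0 == "1D"),
    class_1E = as.numeric(df$risk_class0 == "1E"),
    abort_input(paste0("unknown design term: ", term))
  )
}

# Design matrix with one column per term, rows matching df.
design_matrix_terms <- function(df, terms) {
  X <- vapply(terms, term_column, numeric(nrow(df)), df = df)
  if (nrow(df) == 1L) X <- matrix(X, nrow = 1, dimnames = list(NULL, terms))
  X
}

#' Design row for one patient at one prediction time
#'
#' Expands a patient's baseline covariates at follow-up time `t` into the
#' named term-value map of the Mayo-form model: baseline predictors, linear
#' time, and time-by-predictor interactions (all interaction values are
#' `t` times the corresponding baseline value, hence 0 at `t = 0`).
#'
#' @param baseline One-row data frame or list with `age0`, `sex`
#'   (`"female"`/`"male"`), `egfr0`, and `httkv0` (continuous mode) or
#'   `risk_class0` (class mode).
#' @param t Years since baseline, non-negative.
#' @inheritParams model_coefficients
#' @return Named numeric vector over [model_terms()] for `mode`.
#' @export
design_row <- function(baseline, t,
                       mode = c("continuous_httkv", "risk_class")) {
  mode <- match.arg(mode)
  assert_that(is_scalar_number(t) && t >= 0, "t must be a non-negative number")
  field <- function(nm) if (nm %in% names(baseline)) baseline[[nm]] else NULL
  httkv0 <- field("httkv0")
  if (mode == "continuous_httkv" && (is.null(httkv0) || is.na(httkv0))) {
    abort_input("continuous_httkv mode requires a non-missing httkv0")
  }
  df <- tibble(
    log2_httkv = if (is.null(httkv0)) NA_real_ else log2(httkv0),
    age0 = baseline[["age0"]],
    sex_num = as.numeric(match_sex(baseline[["sex"]]) == "female"),
    egfr0 = baseline[["egfr0"]],
    t_years = t,
    risk_class0 = if (!is.null(field("risk_class0")))
      as.character(field("risk_class0")) else NA_character_
  )
  terms <- model_terms(mode)
  drop(design_matrix_terms(df, terms)[1, ])
}

# Visit-level modelling frame: visits joined to baselines with the numeric
# covariates the design needs. The HtTKV value feeding the log2_httkv term
# follows coeffs$httkv_source; rows whose required values are missing are
# dropped and counted.
build_visit_frame <- function(coeffs, cohort) {
  df <- dplyr::left_join(cohort$visits, cohort$baselines, by = "patient_id")
  df$sex_num <- as.numeric(df$sex == "female")
  need_second <- coeffs$httkv_source == "second_measurement" ||
    any(grepl("second", names(coeffs$beta)))
  if (need_second) {
    sec <- second_httkv_table(cohort)
    df <- dplyr::left_join(df, sec, by = "patient_id")
    df$log2_httkv_second <- log2(df$httkv_second)
  }
  df$log2_httkv <- switch(coeffs$httkv_source,
    baseline = log2(df$httkv0),
    second_measurement = df$log2_httkv_second,
    time_varying = log2(df$httkv)
  )
  used <- names(coeffs$beta)
  need_cols <- c("log2_httkv"[any(c("log2_httkv", "t_log2_httkv") %in% used)],
                 "log2_httkv_second"[any(grepl("second", used))])
  keep <- rep(TRUE, nrow(df))
  for (cc in need_cols) keep <- keep & !is.na(df[[cc]])
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  attr(df, "n_dropped") <- dropped
  df
}

# First follow-up visit with a non-missing HtTKV, per patient.
second_httkv_table <- function(cohort) {
  v <- cohort$visits[!is.na(cohort$visits$httkv), , drop = FALSE]
  v <- v[order(v$patient_id, v$t_years), , drop = FALSE]
  first <- !duplicated(v$patient_id)
  tibble(patient_id = v$patient_id[first],
         httkv_second = v$httkv[first],
         t_second = v$t_years[first])
}

#' Fit the Mayo-form development model on a cohort
#'
#' Fits the linear mixed model \eqn{eGFR_{it} = x_{it}\beta + b_i t +
#' \varepsilon_{it}} with a subject-specific random slope on years of
#' follow-up (no random intercept by default) via [lme4::lmer()].
#' Maximum likelihood is the default so that AIC comparisons across
#' fixed-effect structures are meaningful; REML is available for variance
#' estimation free of fixed-effect degrees of freedom.
#'
#' @param cohort A [long_cohort()].
#' @inheritParams model_coefficients
#' @param reml Use REML instead of ML. Default `FALSE` (ML).
#' @param random_intercept Add a correlated subject-specific intercept
#'   (sensitivity-analysis variant). The returned object still reports the
#'   slope and residual variances; the full covariance is kept as an
#'   attribute.
#' @return An `egfr_model_coefficients` object with `loglik`, `n_obs`,
#'   `n_params` and `fit_method` attributes.
#' @export
fit_development_model <- function(cohort,
                                  mode = c("continuous_httkv", "risk_class"),
                                  reml = FALSE, random_intercept = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "adpkd_long_cohort"))
  terms <- model_terms(mode)
  shell <- model_coefficients(mode, setNames(numeric(length(terms)), terms),
                              1, 1)
  df <- build_visit_frame(shell, cohort)
  if (mode == "continuous_httkv" && any(is.na(df$log2_httkv))) {
    abort_input("missing baseline HtTKV; impute or drop before fitting")
  }
  X <- design_matrix_terms(df, terms)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- terms[-seq_len(qrX$rank)]
    abort_input(paste0(
      "singular fixed-effect design; aliased or constant terms: ",
      paste(setdiff(terms, terms[qr(X)$pivot[seq_len(qrX$rank)]]),
            collapse = ", "),
      " (e.g. a single-sex cohort makes the sex term inestimable)"),
      class = "adpkdval_fit_error")
  }
  dat <- cbind(as.data.frame(X),
               data.frame(egfr_obs = df$egfr_obs,
                          t_years = df$t_years,
                          patient_id = df$patient_id))
  re <- if (random_intercept) "(1 + t_years | patient_id)" else
    "(0 + t_years | patient_id)"
  fml <- stats::as.formula(paste("egfr_obs ~ 0 +",
                                 paste(terms, collapse = " + "), "+", re))
  fit <- lme4::lmer(fml, data = dat, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  beta <- lme4::fixef(fit)[terms]
  vc <- lme4::VarCorr(fit)
  var_slope <- vc$patient_id["t_years", "t_years"]
  out <- model_coefficients(mode, beta, var_slope, stats::sigma(fit)^2)
  ll <- logLik(fit)
  attr(out, "loglik") <- as.numeric(ll)
  attr(out, "n_params") <- attr(ll, "df")
  attr(out, "n_obs") <- nrow(dat)
  attr(out, "fit_method") <- if (reml) "REML" else "ML"
  if (random_intercept) attr(out, "random_cov") <- vc$patient_id
  out
}

#' Predict eGFR at t years from baseline covariates
#'
#' Population-level prediction (subject-specific random slope at its zero
#' mean): `egfr_pred = x(t) . beta`, with marginal predictive standard
#' deviation `sqrt(t^2 * var_random_slope + var_residual)`.
#'
#' @param coeffs An `egfr_model_coefficients` object (baseline HtTKV source).
#' @inheritParams design_row
#' @return A one-row tibble: `patient_id`, `t`, `egfr_pred`, `pred_sd`.
#' @export
predict_egfr <- function(coeffs, baseline, t) {
  stopifnot(inherits(coeffs, "egfr_model_coefficients"))
  if (!is_scalar_number(t) || t < 0) {
    abort_input("t must be a non-negative number", "adpkdval_domain_error")
  }
  x <- design_row(baseline, t, coeffs$mode)
  extra <- setdiff(names(coeffs$beta), names(x))
  if (length(extra) > 0) {
    abort_input(paste0("coefficients carry visit-level terms (",
                       paste(extra, collapse = ", "),
                       "); use predict_cohort() for updated models"))
  }
  tibble(
    patient_id = if ("patient_id" %in% names(baseline))
      baseline[["patient_id"]] else NA_character_,
    t = t,
    egfr_pred = drop(x[names(coeffs$beta)] %*% coeffs$beta),
    pred_sd = sqrt(t^2 * coeffs$var_random_slope + coeffs$var_residual)
  )
}

#' Predict eGFR for every visit of a cohort
#'
#' Applies a coefficient set to all follow-up visits. The HtTKV value used by
#' the `log2_httkv` term follows the coefficient set's `httkv_source`
#' (baseline, per-patient second measurement, or the time-varying visit
#' value); second-measurement terms added by [partial_update()] are filled
#' per patient. Visits whose required HtTKV value is missing are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @inheritParams predict_egfr
#' @param cohort A [long_cohort()].
#' @return Tibble with `patient_id`, `t`, `egfr_pred`, `pred_sd`, `egfr_obs`;
#'   attribute `n_dropped`.
#' @export
predict_cohort <- function(coeffs, cohort) {
  stopifnot(inherits(coeffs, "egfr_model_coefficients"),
            inherits(cohort, "adpkd_long_cohort"))
  df <- build_visit_frame(coeffs, cohort)
  X <- design_matrix_terms(df, names(coeffs$beta))
  out <- tibble(
    patient_id = df$patient_id,
    t = df$t_years,
    egfr_pred = drop(X %*% coeffs$beta),
    pred_sd = sqrt(df$t_years^2 * coeffs$var_random_slope +
                     coeffs$var_residual),
    egfr_obs = df$egfr_obs
  )
  attr(out, "n_dropped") <- attr(df, "n_dropped")
  out
}

#' Marginal log-likelihood of a coefficient set on a cohort
#'
#' Evaluates the exact marginal Gaussian log-likelihood of the random-slope
#' model, integrating the subject-specific slope out analytically: per
#' patient \eqn{y_i \sim N(X_i\beta,\ \sigma^2 I + \sigma^2_b t_i t_i')}.
#' The rank-one covariance makes determinant and inverse closed-form.
#' Used to score frozen external coefficient sets on validation data (their
#' likelihood is not a by-product of any fit) and as an independent
#' likelihood oracle in the tests.
#'
#' @inheritParams predict_cohort
#' @return Scalar log-likelihood; attribute `n_obs`.
#' @export
marginal_loglik <- function(coeffs, cohort) {
  df <- build_visit_frame(coeffs, cohort)
  X <- design_matrix_terms(df, names(coeffs$beta))
  r <- df$egfr_obs - drop(X %*% coeffs$beta)
  marginal_loglik_resid(r, df$t_years, df$patient_id,
                        coeffs$var_random_slope, coeffs$var_residual)
}

# Core rank-one marginal log-likelihood on residuals.
marginal_loglik_resid <- function(r, t, id, var_slope, var_resid) {
  ll <- 0
  for (g in split(seq_along(r), id)) {
    ri <- r[g]; ti <- t[g]; n <- length(g)
    st2 <- sum(ti^2)
    denom <- var_resid + var_slope * st2
    quad <- sum(ri^2) / var_resid -
      (var_slope / (var_resid * denom)) * sum(ri * ti)^2
    logdet <- n * log(var_resid) + log1p(var_slope * st2 / var_resid)
    ll <- ll - 0.5 * (n * log(2 * pi) + logdet + quad)
  }
  structure(ll, n_obs = length(r))
}

#' Write / read model coefficients as JSON
#'
#' Serialises the exact term names, variance components and HtTKV source, so
#' externally published coefficient sets can be loaded into the same schema
#' rather than hard-coded.
#'
#' @param coeffs An `egfr_model_coefficients` object.
#' @param path File path.
#' @return `write_coefficients` returns `path` invisibly; `read_coefficients`
#'   returns the coefficient object.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "egfr_model_coefficients"))
  jsonlite::write_json(list(
    mode = coeffs$mode,
    beta = as.list(coeffs$beta),
    var_random_slope = coeffs$var_random_slope,
    var_residual = coeffs$var_residual,
    httkv_source = coeffs$httkv_source
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_coefficients(x$mode, unlist(x$beta), x$var_random_slope,
                     x$var_residual, httkv_source = x$httkv_source)
}
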