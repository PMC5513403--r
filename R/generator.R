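#' Generating truth coefficients for synthetic cohorts
#'
#' Default fixed effects and variance components used as the data-generating
#' truth. The values are chosen so that the synthetic cohorts look like a
#' typical adult ADPKD population: mean eGFR decline around 3-4
#' ml/min/1.73m^2 per year at the median kidney volume, steeper decline for
#' larger kidneys, between-patient slope SD of 2 and residual SD of 5
#' ml/min/1.73m^2.
#'
#' `swiss_truth_coefficients()` is the same model with the log2-HtTKV main
#' and time-interaction coefficients shifted (-2.5 to -3.0 and -0.35 to
#' -0.40). It emulates a validation population in which the kidney-volume
#' term is mis-calibrated relative to the development setting, as can arise
#' from a different TKV assessment method; this is what gives coefficient
#' updating something real to correct.
#'
#' @return An `egfr_model_coefficients` object in `continuous_httkv` mode.
#' @export
default_truth_coefficients <- function() {
  model_coefficients(
    "continuous_httkv",
    beta = c(intercept = 39, log2_httkv = -2.5, age0 = -0.15, sex = 1,
             egfr0 = 0.85, t = 0, t_log2_httkv = -0.35, t_age0 = 0.01,
             t_sex = 0.1, t_egfr0 = -0.01),
    var_random_slope = 4, var_residual = 25)
}

#' @rdname default_truth_coefficients
#' @export
swiss_truth_coefficients <- function() {
  truth <- default_truth_coefficients()
  truth$beta["log2_httkv"] <- -3.0
  truth$beta["t_log2_httkv"] <- -0.40
  truth
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the published structure of the Swiss ADPKD validation
#' sample: n = 214 patients, baseline age median 34 (IQR 27-40) years, eGFR
#' median 82 (IQR 70-95) ml/min/1.73m^2, HtTKV median 497 (IQR 317-762)
#' ml/m (log-normal), 44% female, a second visit within 6-12 months then
#' annual visits with scheduling jitter, per-patient follow-up uniform on
#' 0.42-10.28 years, exponential per-patient kidney growth spanning classes
#' 1A-1E, linear eGFR decline with subject-specific slopes, 8% multiplicative
#' HtTKV measurement noise, and 3% MCAR missingness in follow-up HtTKV.
#'
#' @param n_patients Number of patients (>= 0).
#' @param seed Master seed; every random sub-stream derives from it.
#' @param age_quartiles,egfr0_quartiles Length-5 vectors (min, Q1, median,
#'   Q3, max) defining piecewise-linear quantile samplers; baseline age in
#'   years must stay above 18 and eGFR above 30 (eligibility).
#' @param frac_female Fraction of female patients in \[0, 1\].
#' @param height_mean,height_sd Named (`female`, `male`) normal parameters
#'   for height in metres.
#' @param httkv0_meanlog,httkv0_sdlog Log-normal parameters for baseline
#'   HtTKV (ml/m); the defaults give median 497 and IQR approx 319-774.
#' @param growth_mult_meanlog,growth_mult_sdlog Log-normal parameters of the
#'   per-patient multiplier linking the true yearly kidney growth rate to
#'   the class-typical rate implied by the patient's baseline age and HtTKV
#'   (`true rate = implied rate x multiplier`). The default multiplier
#'   median of 2 makes current growth outpace the lifetime average, so
#'   risk-class progression dominates regression over follow-up, as seen in
#'   young ADPKD cohorts.
#' @param egfr_model_truth `egfr_model_coefficients` used as generating
#'   truth; its `var_random_slope` drives the subject-specific slopes.
#' @param visit_gap_first Bounds (years) of the uniform first follow-up
#'   visit time; default `c(0.5, 1)` (second study visit within 6-12 months).
#' @param visit_jitter Half-width (years) of the uniform jitter on annual
#'   visits thereafter.
#' @param followup_min,max_followup Bounds (years) of the uniform per-patient
#'   administrative follow-up.
#' @param httkv_noise_cv Coefficient of variation of multiplicative
#'   (mean-one log-normal) HtTKV measurement noise.
#' @param egfr_noise_sd Residual SD of observed eGFR (ml/min/1.73m^2).
#' @param dropout_egfr Follow-up stops after the first visit whose observed
#'   eGFR falls below this threshold (ml/min/1.73m^2), emulating progression
#'   to advanced CKD ending study participation. Dropout triggered by an
#'   observed value is missing-at-random, so likelihood-based model fits
#'   remain unbiased. Set to 0 to disable.
#' @param missing_rate MCAR missingness probability for follow-up HtTKV.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 214,
                             seed = 1L,
                             age_quartiles = c(19, 27, 34, 40, 55),
                             frac_female = 94 / 214,
                             height_mean = c(female = 1.66, male = 1.78),
                             height_sd = c(female = 0.065, male = 0.07),
                             egfr0_quartiles = c(31, 70, 82, 95, 130),
                             httkv0_meanlog = log(497),
                             httkv0_sdlog = 0.65,
                             growth_mult_meanlog = log(2),
                             growth_mult_sdlog = 0.25,
                             egfr_model_truth = swiss_truth_coefficients(),
                             visit_gap_first = c(0.5, 1.0),
                             visit_jitter = 0.15,
                             followup_min = 0.42,
                             max_followup = 10.28,
                             httkv_noise_cv = 0.08,
                             egfr_noise_sd = 5,
                             dropout_egfr = 15,
                             missing_rate = 0.03) {
  cfg <- list(n_patients = n_patients, seed = as.integer(seed),
              age_quartiles = age_quartiles, frac_female = frac_female,
              height_mean = height_mean, height_sd = height_sd,
              egfr0_quartiles = egfr0_quartiles,
              httkv0_meanlog = httkv0_meanlog, httkv0_sdlog = httkv0_sdlog,
              growth_mult_meanlog = growth_mult_meanlog,
              growth_mult_sdlog = growth_mult_sdlog,
              egfr_model_truth = egfr_model_truth,
              visit_gap_first = visit_gap_first, visit_jitter = visit_jitter,
              followup_min = followup_min, max_followup = max_followup,
              httkv_noise_cv = httkv_noise_cv, egfr_noise_sd = egfr_noise_sd,
              dropout_egfr = dropout_egfr, missing_rate = missing_rate)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  assert_that(is_scalar_number(cfg$n_patients) && cfg$n_patients >= 0,
              "n_patients must be >= 0")
  for (f in c("frac_female", "missing_rate")) {
    assert_that(is_scalar_number(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
                paste(f, "must be a fraction in [0, 1]"))
  }
  for (f in c("httkv_noise_cv", "egfr_noise_sd", "visit_jitter",
              "dropout_egfr")) {
    assert_that(is_scalar_number(cfg[[f]]) && cfg[[f]] >= 0,
                paste(f, "must be >= 0"))
  }
  assert_that(is_scalar_number(cfg$max_followup) && cfg$max_followup >= 0,
              "max_followup must be >= 0")
  assert_that(cfg$followup_min > 0 && cfg$followup_min <= cfg$max_followup,
              "followup_min must be positive and <= max_followup")
  assert_that(all(cfg$age_quartiles > 18) && !is.unsorted(cfg$age_quartiles),
              "age_quartiles must be sorted and exceed 18 (eligibility)")
  assert_that(all(cfg$egfr0_quartiles > 30) &&
                !is.unsorted(cfg$egfr0_quartiles),
              "egfr0_quartiles must be sorted and exceed 30 (eligibility)")
  assert_that(all(cfg$height_sd >= 0) && all(cfg$height_mean > 0),
              "height distribution parameters must be positive")
  assert_that(all(cfg$visit_gap_first > 0) &&
                cfg$visit_gap_first[1] <= cfg$visit_gap_first[2],
              "visit_gap_first must be positive increasing bounds")
  assert_that(inherits(cfg$egfr_model_truth, "egfr_model_coefficients"),
              "egfr_model_truth must be an egfr_model_coefficients object")
  invisible(cfg)
}

#' Mayo-development-like generator configuration
#'
#' The same generator pointed at the published structure of the Mayo Clinic
#' development sample: n = 376, baseline age median 44 (IQR 35-51) years,
#' eGFR median 71 (IQR 44-97), HtTKV median 651 (IQR 431-1195) ml/m, 62%
#' female, follow-up 1-11 years, and the unshifted generating truth.
#'
#' @param n_patients Number of patients.
#' @param seed Master seed.
#' @param ... Further overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
mayo_generator_config <- function(n_patients = 376, seed = 1L, ...) {
  generator_config(
    n_patients = n_patients, seed = seed,
    age_quartiles = c(19, 35, 44, 51, 70),
    frac_female = 232 / 376,
    egfr0_quartiles = c(31, 44, 71, 97, 130),
    httkv0_meanlog = log(651),
    httkv0_sdlog = log(1195 / 431) / 2 / qnorm(0.75),
    egfr_model_truth = default_truth_coefficients(),
    followup_min = 1, max_followup = 11,
    ...)
}

#' Serialise / load a generator configuration as JSON
#'
#' Flat key/value serialisation with keys exactly matching the
#' [generator_config()] fields; the generating truth is embedded with its
#' term names.
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` returns the configuration.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  for (f in c("height_mean", "height_sd")) x[[f]] <- as.list(x[[f]])
  tr <- x$egfr_model_truth
  x$egfr_model_truth <- list(mode = tr$mode, beta = as.list(tr$beta),
                             var_random_slope = tr$var_random_slope,
                             var_residual = tr$var_residual)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- x$egfr_model_truth
  x$egfr_model_truth <- model_coefficients(tr$mode, unlist(tr$beta),
                                           tr$var_random_slope,
                                           tr$var_residual)
  for (f in c("height_mean", "height_sd")) x[[f]] <- unlist(x[[f]])
  do.call(generator_config, x)
}

#' Generate a synthetic longitudinal ADPKD cohort
#'
#' Seeded, fully reproducible generation: baseline covariates from the
#' configured distributions (eligibility enforced by construction), visit
#' schedules (first follow-up within the configured 6-12 month window, then
#' annual with jitter, truncated at per-patient follow-up), HtTKV
#' trajectories `httkv0 * (1 + rate)^t` with mean-one multiplicative noise,
#' observed eGFR from the generating truth's fixed effects plus a
#' subject-specific random slope and residual noise, and MCAR missingness in
#' follow-up HtTKV. Observed eGFR is floored at 0.5 ml/min/1.73m^2 to keep
#' it positive (relevant to well under 1% of visits at the default noise).
#'
#' @param config A [generator_config()].
#' @return A [long_cohort()] whose baselines carry the synthetic-only truth
#'   columns `true_growth_rate` and `true_slope_dev` (hidden from analysis
#'   stages and never serialised).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n <- as.integer(config$n_patients)
  truth <- config$egfr_model_truth
  if (n == 0) {
    b <- tibble(patient_id = character(0), sex = character(0),
                age0 = numeric(0), height_m = numeric(0),
                creatinine0 = numeric(0), egfr0 = numeric(0),
                httkv0 = numeric(0), true_growth_rate = numeric(0),
                true_slope_dev = numeric(0))
    v <- tibble(patient_id = character(0), t_years = numeric(0),
                egfr_obs = numeric(0), httkv = numeric(0))
    return(long_cohort(b, v))
  }
  set.seed(derive_seed(config$seed, 0))
  sex <- ifelse(runif(n) < config$frac_female, "female", "male")
  age0 <- sample_piecewise_quantiles(n, config$age_quartiles)
  height <- rnorm(n, config$height_mean[sex], config$height_sd[sex])
  egfr0 <- sample_piecewise_quantiles(n, config$egfr0_quartiles)
  httkv0 <- rlnorm(n, config$httkv0_meanlog, config$httkv0_sdlog)
  implied_rate <- estimated_growth_rate(httkv0, age0)
  rate <- implied_rate * rlnorm(n, config$growth_mult_meanlog,
                                config$growth_mult_sdlog)
  slope_dev <- rnorm(n, 0, sqrt(truth$var_random_slope))
  baselines <- tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = sex, age0 = age0, height_m = height,
    creatinine0 = ckd_epi_creatinine(egfr0, age0, sex),
    egfr0 = egfr0, httkv0 = httkv0,
    true_growth_rate = rate, true_slope_dev = slope_dev)

  # Visit schedule: first follow-up uniform in visit_gap_first, then annual
  # with +/- visit_jitter, truncated at a per-patient follow-up horizon; the
  # first follow-up visit is always kept (>= 1 follow-up per patient).
  set.seed(derive_seed(config$seed, 1))
  followup <- runif(n, config$followup_min, config$max_followup)
  times <- lapply(seq_len(n), function(i) {
    t1 <- runif(1, config$visit_gap_first[1], config$visit_gap_first[2])
    k <- seq_len(max(0, floor(config$max_followup - t1)))
    later <- t1 + k + runif(length(k), -config$visit_jitter,
                            config$visit_jitter)
    c(t1, later[later <= followup[i]])
  })
  visits <- tibble(
    patient_id = rep(baselines$patient_id, lengths(times)),
    t_years = unlist(times))

  set.seed(derive_seed(config$seed, 2))
  idx <- match(visits$patient_id, baselines$patient_id)
  visits$httkv <- simulate_httkv_values(
    httkv0[idx], rate[idx], visits$t_years, config$httkv_noise_cv)

  set.seed(derive_seed(config$seed, 3))
  df <- tibble(log2_httkv = log2(httkv0[idx]), age0 = age0[idx],
               sex_num = as.numeric(sex[idx] == "female"),
               egfr0 = egfr0[idx], t_years = visits$t_years)
  fixed <- drop(design_matrix_terms(df, names(truth$beta)) %*% truth$beta)
  visits$egfr_obs <- pmax(
    fixed + slope_dev[idx] * visits$t_years +
      rnorm(nrow(visits), 0, config$egfr_noise_sd),
    0.5)
  if (config$dropout_egfr > 0) {
    keep <- unlist(tapply(
      visits$egfr_obs, factor(visits$patient_id,
                              levels = baselines$patient_id),
      function(y) {
        hit <- which(y < config$dropout_egfr)
        seq_along(y) <= if (length(hit)) max(hit[1], 1L) else length(y)
      }), use.names = FALSE)
    visits <- visits[keep, , drop = FALSE]
  }
  visits <- visits[, c("patient_id", "t_years", "egfr_obs", "httkv")]
  cohort <- long_cohort(baselines, visits)
  apply_missingness(cohort, config$missing_rate,
                    seed = derive_seed(config$seed, 4))
}

# Noisy exponential-growth HtTKV values; expectation httkv0 * (1 + rate)^t.
simulate_httkv_values <- function(httkv0, rate, times, noise_cv) {
  mu <- httkv0 * (1 + rate)^times
  if (noise_cv == 0) return(mu)
  sdlog <- sqrt(log(1 + noise_cv^2))
  mu * rlnorm(length(mu), -sdlog^2 / 2, sdlog)
}

#' Simulate one HtTKV trajectory
#'
#' Exponential kidney growth `httkv0 * (1 + rate)^t` with mean-one
#' multiplicative log-normal measurement noise of coefficient of variation
#' `noise_cv`; `noise_cv = 0` returns the deterministic curve.
#'
#' @param httkv0 Baseline HtTKV in ml/m, positive.
#' @param rate Yearly fractional growth rate, > -1.
#' @param times Numeric vector of non-negative times in years.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Optional seed for reproducibility.
#' @return Numeric vector of HtTKV values (ml/m), one per time.
#' @export
simulate_httkv_trajectory <- function(httkv0, rate, times, noise_cv = 0,
                                      seed = NULL) {
  if (!is_scalar_number(httkv0) || httkv0 <= 0) {
    abort_input("httkv0 must be positive", "adpkdval_domain_error")
  }
  if (!is_scalar_number(rate) || rate <= -1) {
    abort_input("rate must exceed -1", "adpkdval_domain_error")
  }
  if (any(times < 0)) {
    abort_input("times must be non-negative", "adpkdval_domain_error")
  }
  assert_that(is_scalar_number(noise_cv) && noise_cv >= 0,
              "noise_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  simulate_httkv_values(rep(httkv0, length(times)), rate, times, noise_cv)
}

#' Apply MCAR missingness to follow-up HtTKV
#'
#' Each follow-up visit's HtTKV is independently set missing with the given
#' probability; baseline HtTKV is never removed.
#'
#' @param cohort A [long_cohort()].
#' @param rate Missingness probability in \[0, 1\].
#' @param seed Optional seed.
#' @return The cohort with missing follow-up HtTKV values.
#' @export
apply_missingness <- function(cohort, rate, seed = NULL) {
  stopifnot(inherits(cohort, "adpkd_long_cohort"))
  assert_that(is_scalar_number(rate) && rate >= 0 && rate <= 1,
              "rate must be a fraction in [0, 1]")
  if (rate == 0 || nrow(cohort$visits) == 0) return(cohort)
  if (!is.null(seed)) set.seed(seed)
  drop_it <- runif(nrow(cohort$visits)) < rate
  cohort$visits$httkv[drop_it] <- NA_real_
  cohort
}
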