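# Shared fixture builders. All data are generated in code; no files.

# Fully deterministic generator settings: no measurement noise, no residual
# noise, no between-patient slope variation, no missingness.
noiseless_config <- function(n = 30, seed = 1, truth = NULL, ...) {
  if (is.null(truth)) {
    truth <- swiss_truth_coefficients()
    truth$var_random_slope <- 0
  }
  generator_config(n_patients = n, seed = seed, egfr_model_truth = truth,
                   httkv_noise_cv = 0, egfr_noise_sd = 0, missing_rate = 0,
                   ...)
}

# Same but with zero kidney growth, so time-varying HtTKV equals baseline.
zero_growth_config <- function(n = 30, seed = 1, ...) {
  noiseless_config(n = n, seed = seed,
                   growth_mult_meanlog = log(1e-9), growth_mult_sdlog = 0, ...)
}

# Growth at exactly the baseline-implied rate: risk class is stationary.
class_stationary_config <- function(n = 30, seed = 1, ...) {
  noiseless_config(n = n, seed = seed,
                   growth_mult_meanlog = 0, growth_mult_sdlog = 0, ...)
}

# Tiny hand-built cohort: 3 patients, 2 visits each.
tiny_cohort <- function() {
  b <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    sex = c("female", "male", "female"),
    age0 = c(30, 45, 38),
    height_m = c(1.65, 1.80, 1.70),
    creatinine0 = c(0.8, 1.1, 0.9),
    egfr0 = c(95, 70, 85),
    httkv0 = c(400, 800, 550))
  v <- tibble::tibble(
    patient_id = rep(c("A", "B", "C"), each = 2),
    t_years = rep(c(1, 2), 3),
    egfr_obs = c(92, 90, 66, 63, 83, 80),
    httkv = c(420, 440, NA, 880, 570, 590))
  long_cohort(b, v)
}

# Mean-one-noise patient-level fixture with a known class crossing:
# starts just inside 1A at age 40 and ends just inside 1B five years later.
crossing_cohort <- function(n = 10) {
  h0 <- class_boundary_httkv(40, 0.015) * 0.99
  h5 <- class_boundary_httkv(45, 0.015) * 1.01
  b <- tibble::tibble(
    patient_id = sprintf("X%02d", seq_len(n)), sex = "male", age0 = 40,
    height_m = 1.8, creatinine0 = 1.0, egfr0 = 80, httkv0 = h0)
  v <- tibble::tibble(patient_id = b$patient_id, t_years = 5,
                      egfr_obs = 70, httkv = h5)
  long_cohort(b, v)
}
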