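# Synthetic cohort generator: reproducibility, eligibility, distributional
# targets, trajectory model, missingness, CSV round trips.

test_that("empty request yields an empty cohort without error", {
  co <- generate_cohort(generator_config(n_patients = 0))
  expect_s3_class(co, "adpkd_long_cohort")
  expect_equal(nrow(co$baselines), 0)
  expect_equal(nrow(co$visits), 0)
})

test_that("identical configuration gives a byte-identical cohort CSV", {
  cfg <- generator_config(n_patients = 50, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg), f1)
  write_cohort(generate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated baselines respect eligibility and structure", {
  co <- generate_cohort(generator_config(n_patients = 300, seed = 2))
  b <- co$baselines
  expect_true(all(b$age0 > 18))
  expect_true(all(b$egfr0 > 30))
  expect_true(all(b$httkv0 > 0))
  expect_true(all(b$height_m > 0))
  # every patient has at least one follow-up visit, strictly increasing times
  expect_setequal(unique(co$visits$patient_id), b$patient_id)
  expect_true(all(tapply(co$visits$t_years, co$visits$patient_id,
                         function(tt) all(diff(c(0, tt)) > 0))))
  # creatinine is consistent with baseline eGFR through the CKD-EPI inverse
  expect_equal(ckd_epi_egfr(b$creatinine0, b$age0, b$sex), b$egfr0,
               tolerance = 1e-8)
})

test_that("baseline medians land near the emulated cohort targets", {
  co <- generate_cohort(generator_config(n_patients = 2000, seed = 11))
  b <- co$baselines
  expect_lt(abs(median(b$age0) - 34) / 34, 0.10)
  expect_lt(abs(median(b$egfr0) - 82) / 82, 0.10)
  expect_lt(abs(median(b$httkv0) - 497) / 497, 0.10)
})

test_that("noiseless generation reproduces the fixed-effect model exactly", {
  cfg <- noiseless_config(n = 25, seed = 9)
  co <- generate_cohort(cfg)
  pr <- predict_cohort(cfg$egfr_model_truth, co)
  expect_identical(pr$egfr_obs, pr$egfr_pred)
})

test_that("HtTKV trajectories follow exponential growth", {
  expect_equal(simulate_httkv_trajectory(200, 0, c(0, 5, 10), 0),
               c(200, 200, 200))
  expect_equal(simulate_httkv_trajectory(200, 0.03, 10, 0), 200 * 1.03^10,
               tolerance = 1e-12)
  # Monte-Carlo mean of the multiplicative noise model
  set.seed(99)
  draws <- simulate_httkv_trajectory(200, 0.03, rep(10, 1e4), 0.05)
  expect_lt(abs(mean(draws) - 200 * 1.03^10) / (200 * 1.03^10), 0.01)
  expect_error(simulate_httkv_trajectory(200, 0.03, -1, 0),
               class = "adpkdval_domain_error")
  expect_error(simulate_httkv_trajectory(-5, 0.03, 1, 0),
               class = "adpkdval_domain_error")
})

test_that("missingness is MCAR at the requested rate and spares baselines", {
  co <- generate_cohort(generator_config(n_patients = 2000, seed = 3,
                                         missing_rate = 0))
  expect_identical(apply_missingness(co, 0), co)
  all_gone <- apply_missingness(co, 1)
  expect_true(all(is.na(all_gone$visits$httkv)))
  expect_true(all(!is.na(all_gone$baselines$httkv0)))
  n <- nrow(co$visits)
  punched <- apply_missingness(co, 0.03, seed = 5)
  frac <- mean(is.na(punched$visits$httkv))
  expect_lt(abs(frac - 0.03), 3 * sqrt(0.03 * 0.97 / n))
})

test_that("cohort CSV round trip is the identity on serialised fields", {
  co <- generate_cohort(generator_config(n_patients = 40, seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$visits, co$visits)
  keep <- setdiff(names(back$baselines), "risk_class0")
  expect_equal(back$baselines[keep],
               co$baselines[keep])
  expect_equal(back$baselines$risk_class0, co$baselines$risk_class0)
  # missing HtTKV encoded as empty fields, count preserved
  expect_equal(sum(is.na(back$visits$httkv)), sum(is.na(co$visits$httkv)))
})

test_that("malformed cohort files raise parse errors naming the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- generate_cohort(generator_config(n_patients = 5, seed = 1))
  write_cohort(co, path)
  bad <- readLines(path)
  bad[1] <- sub("httkv0", "httkv_zero", bad[1])
  writeLines(bad, path)
  expect_error(read_cohort(path), "httkv",
               class = "adpkdval_parse_error")
})

test_that("configuration errors are caught", {
  expect_error(generator_config(n_patients = -1))
  expect_error(generator_config(missing_rate = 1.5))
  expect_error(generator_config(httkv_noise_cv = -0.1))
  expect_error(generator_config(age_quartiles = c(10, 27, 34, 40, 55)))
})

test_that("generator config JSON round trip preserves every field", {
  cfg <- generator_config(n_patients = 17, seed = 23, missing_rate = 0.07)
  path <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$egfr_model_truth$beta, cfg$egfr_model_truth$beta)
  back$egfr_model_truth <- cfg$egfr_model_truth <- NULL
  expect_equal(unclass(back), unclass(cfg))
})
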