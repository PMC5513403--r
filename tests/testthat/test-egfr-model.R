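# Mixed-model representation: design, fitting, prediction, partial updates.

test_that("design rows expand baseline covariates with time interactions", {
  b <- list(httkv0 = 512, age0 = 40, sex = "female", egfr0 = 90)
  x0 <- design_row(b, 0, "continuous_httkv")
  expect_equal(x0[["log2_httkv"]], 9)  # 2^9 = 512
  expect_true(all(x0[startsWith(names(x0), "t")] == 0))
  x3 <- design_row(b, 3, "continuous_httkv")
  expect_equal(x3[["t_log2_httkv"]], 27)
  expect_equal(x3[["t_sex"]], 3)
  expect_equal(x3[["sex"]], 1)  # female = 1
  # class mode: a 1A patient is all-reference
  b$risk_class0 <- "1A"
  xc <- design_row(b, 2, "risk_class")
  expect_true(all(xc[grep("class_", names(xc))] == 0))
  b$risk_class0 <- "1D"
  xd <- design_row(b, 2, "risk_class")
  expect_equal(xd[["class_1D"]], 1)
  expect_equal(xd[["t_class_1D"]], 2)
  expect_error(design_row(list(age0 = 40, sex = "male", egfr0 = 80), 1,
                          "continuous_httkv"),
               "httkv0")
})

test_that("prediction is the dot product of design row and coefficients", {
  terms <- model_terms("continuous_httkv")
  set.seed(7)
  beta <- setNames(rnorm(length(terms)), terms)
  cf <- model_coefficients("continuous_httkv", beta, 4, 25)
  b <- list(patient_id = "p", httkv0 = 612, age0 = 37.5, sex = "male",
            egfr0 = 84)
  t <- 4.2
  # brute-force oracle written out longhand, independent of design machinery
  l2 <- log2(612)
  oracle <- beta["intercept"] + beta["log2_httkv"] * l2 +
    beta["age0"] * 37.5 + beta["sex"] * 0 + beta["egfr0"] * 84 +
    beta["t"] * t + beta["t_log2_httkv"] * t * l2 + beta["t_age0"] * t * 37.5 +
    beta["t_sex"] * t * 0 + beta["t_egfr0"] * t * 84
  pr <- predict_egfr(cf, b, t)
  expect_equal(pr$egfr_pred, unname(oracle), tolerance = 1e-10)
  expect_equal(pr$pred_sd, sqrt(t^2 * 4 + 25))
  # intercept-only model returns the intercept at t = 0
  beta0 <- setNames(numeric(length(terms)), terms)
  beta0["intercept"] <- 57.5
  cf0 <- model_coefficients("continuous_httkv", beta0, 1, 1)
  expect_equal(predict_egfr(cf0, b, 0)$egfr_pred, 57.5)
  # degenerate slope variance: constant predictive SD
  cfd <- model_coefficients("continuous_httkv", beta, 0, 25)
  expect_equal(predict_egfr(cfd, b, 8)$pred_sd, 5)
  expect_error(predict_egfr(cf, b, -1), class = "adpkdval_domain_error")
})

test_that("predictive SD is non-decreasing in time and bounded below", {
  cf <- swiss_truth_coefficients()
  b <- list(httkv0 = 500, age0 = 34, sex = "female", egfr0 = 82)
  sds <- vapply(seq(0, 10, by = 0.5),
                function(t) predict_egfr(cf, b, t)$pred_sd, numeric(1))
  expect_true(all(diff(sds) >= 0))
  expect_true(all(sds >= sqrt(cf$var_residual)))
})

test_that("doubling HtTKV shifts predictions by the log2 coefficients", {
  cf <- swiss_truth_coefficients()
  b1 <- list(httkv0 = 400, age0 = 40, sex = "male", egfr0 = 80)
  b2 <- b1; b2$httkv0 <- 800
  for (t in c(0, 2.5, 7)) {
    delta <- predict_egfr(cf, b2, t)$egfr_pred -
      predict_egfr(cf, b1, t)$egfr_pred
    expect_equal(delta,
                 unname(cf$beta["log2_httkv"] + t * cf$beta["t_log2_httkv"]),
                 tolerance = 1e-12)
  }
})

test_that("coefficient container enforces its term contract", {
  terms <- model_terms("continuous_httkv")
  beta <- setNames(rnorm(length(terms)), terms)
  expect_error(model_coefficients("continuous_httkv", beta[-1], 1, 1),
               "missing terms")
  expect_error(model_coefficients("continuous_httkv",
                                  c(beta, bogus = 1), 1, 1),
               "unknown")
  expect_error(model_coefficients("continuous_httkv", beta, -1, 1))
  expect_error(model_coefficients("risk_class", beta, 1, 1), "missing terms")
  # JSON round trip preserves everything
  cf <- model_coefficients("continuous_httkv", beta, 2, 9,
                           httkv_source = "time_varying")
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(cf, path)
  back <- read_coefficients(path)
  expect_equal(back$beta, cf$beta)
  expect_equal(back$var_random_slope, 2)
  expect_equal(back$httkv_source, "time_varying")
})

test_that("a noiseless cohort is refit to the generating coefficients", {
  cfg <- noiseless_config(n = 40, seed = 3)
  co <- generate_cohort(cfg)
  fit <- fit_development_model(co, "continuous_httkv")
  expect_equal(fit$beta, cfg$egfr_model_truth$beta, tolerance = 1e-6)
  # two fits of the same data are identical
  fit2 <- fit_development_model(co, "continuous_httkv")
  expect_identical(fit$beta, fit2$beta)
})

test_that("singular designs are rejected with an informative error", {
  co <- generate_cohort(generator_config(n_patients = 30, seed = 5,
                                         frac_female = 0))
  expect_error(fit_development_model(co, "continuous_httkv"),
               "sex", class = "adpkdval_fit_error")
})

test_that("the hand-coded marginal likelihood matches lme4 at the optimum", {
  co <- generate_cohort(generator_config(n_patients = 60, seed = 8,
                                         missing_rate = 0))
  fit <- fit_development_model(co, "continuous_httkv")
  expect_equal(as.numeric(marginal_loglik(fit, co)), attr(fit, "loglik"),
               tolerance = 1e-5)
})

test_that("partial update refits only the requested terms", {
  truth <- swiss_truth_coefficients()
  co <- generate_cohort(generator_config(n_patients = 80, seed = 10,
                                         missing_rate = 0))
  for (mode in c("model1_two_tkv", "model2_time_varying")) {
    for (wi in c(FALSE, TRUE)) {
      upd <- partial_update(truth, co, mode, with_interaction = wi)
      refit <- attr(upd, "refit_terms")
      frozen <- setdiff(names(truth$beta), refit)
      expect_identical(upd$beta[frozen], truth$beta[frozen])
      expect_true(all(refit %in% names(upd$beta)))
    }
  }
  # model-1 default adds terms; replace-baseline and model 2 do not
  u1 <- partial_update(truth, co, "model1_two_tkv")
  expect_true("log2_httkv_second" %in% names(u1$beta))
  expect_equal(u1$httkv_source, "baseline")
  u1r <- partial_update(truth, co, "model1_two_tkv", replace_baseline = TRUE)
  expect_equal(u1r$httkv_source, "second_measurement")
  u2 <- partial_update(truth, co, "model2_time_varying")
  expect_equal(u2$httkv_source, "time_varying")
  expect_identical(names(u2$beta), names(truth$beta))
})

test_that("partial update is self-consistent on its own noiseless data", {
  cfg <- zero_growth_config(n = 40, seed = 12)
  co <- generate_cohort(cfg)
  truth <- cfg$egfr_model_truth
  upd <- partial_update(truth, co, "model2_time_varying")
  expect_equal(upd$beta[["log2_httkv"]], truth$beta[["log2_httkv"]],
               tolerance = 1e-6)
})

test_that("unsupported update modes and data raise errors", {
  co <- generate_cohort(generator_config(n_patients = 20, seed = 2))
  cls <- fit_development_model(co, "risk_class")
  expect_error(partial_update(cls, co, "model2_time_varying"),
               class = "adpkdval_unsupported_mode")
  truth <- swiss_truth_coefficients()
  all_missing <- apply_missingness(co, 1)
  expect_error(partial_update(truth, all_missing, "model1_two_tkv"),
               "second")
})
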