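# Growth-rate inference, class assignment, boundary curves, transitions.

test_that("estimated growth rate solves the exponential growth equation", {
  expect_equal(estimated_growth_rate(150, 27), 0)
  expect_equal(estimated_growth_rate(150, 63.2), 0)
  # direct arithmetic: 150 * (1 + r)^40 = 600
  expect_equal(estimated_growth_rate(600, 40), 4^(1 / 40) - 1,
               tolerance = 1e-12)
  expect_equal(estimated_growth_rate(600, 40), 0.0352649, tolerance = 1e-6)
  expect_error(estimated_growth_rate(0, 40), class = "adpkdval_domain_error")
  expect_error(estimated_growth_rate(500, 0), class = "adpkdval_domain_error")
})

test_that("class assignment uses left-closed boundaries into the upper class", {
  expect_equal(as.character(assign_class(0.010)), "1A")
  expect_equal(as.character(assign_class(0.020)), "1B")
  expect_equal(as.character(assign_class(0.015)), "1B")
  expect_equal(as.character(assign_class(c(0.030, 0.045, 0.060))),
               c("1C", "1D", "1E"))
  expect_equal(as.character(assign_class(-0.5)), "1A")
  expect_error(assign_class(-1), class = "adpkdval_domain_error")
})

test_that("every finite rate maps to exactly one ordered class", {
  set.seed(1)
  rates <- c(runif(500, -0.9, 0.3), risk_class_breaks,
             risk_class_breaks - 1e-12)
  cls <- assign_class(rates)
  expect_false(anyNA(cls))
  expect_true(is.ordered(cls))
  expect_identical(levels(cls), risk_class_levels)
})

test_that("boundary curves invert the growth-rate estimate", {
  expect_equal(class_boundary_httkv(40, 0.015), 150 * 1.015^40,
               tolerance = 1e-12)
  expect_equal(class_boundary_httkv(40, 0.015), 272.103, tolerance = 1e-5)
  expect_equal(class_boundary_httkv(1e-9, 0.06), 150, tolerance = 1e-6)
  set.seed(2)
  a <- runif(200, 19, 80)
  r <- runif(200, -0.2, 0.15)
  expect_equal(estimated_growth_rate(class_boundary_httkv(a, r), a), r,
               tolerance = 1e-10)
  tab <- boundary_table(ages = c(20, 40, 60))
  expect_equal(nrow(tab), 12)
  expect_equal(tab$httkv_limit,
               150 * (1 + tab$threshold)^tab$age, tolerance = 1e-12)
})

test_that("growth rate is monotone in HtTKV and age", {
  h <- seq(160, 3000, length.out = 100)
  expect_true(all(diff(estimated_growth_rate(h, 40)) > 0))
  a <- seq(19, 80, length.out = 100)
  expect_true(all(diff(estimated_growth_rate(800, a)) < 0))
})

test_that("transitions: class-stationary growth means no class changes", {
  # growth at exactly the baseline-implied rate keeps the implied since-birth
  # rate, and hence the class, constant at every later age
  co <- generate_cohort(class_stationary_config(n = 40, seed = 4))
  ts <- transition_summary(co)
  expect_equal(sum(ts$counts) - sum(diag(ts$counts)), 0)
  expect_equal(ts$pct_progressed, 0)
  expect_equal(ts$pct_regressed, 0)
})

test_that("transitions: a constructed 1A-to-1B crossing is counted in full", {
  ts <- transition_summary(crossing_cohort(10))
  expect_equal(ts$n_assessed, 10)
  expect_equal(ts$counts["1A", "1B"], 10)
  expect_equal(sum(ts$counts), 10)
  expect_equal(ts$pct_progressed, 100)
  expect_equal(ts$pct_regressed, 0)
})

test_that("patients without follow-up HtTKV are excluded from assessment", {
  co <- crossing_cohort(6)
  co$visits$httkv <- NA_real_
  ts <- transition_summary(co)
  expect_equal(ts$n_assessed, 0)
  expect_true(is.na(ts$pct_progressed))
  expect_true(is.na(ts$pct_regressed))
})

test_that("transition row sums equal assessed baseline class counts", {
  co <- generate_cohort(generator_config(n_patients = 120, seed = 6))
  ts <- transition_summary(co)
  cls <- classify_cohort(co)
  assessed <- cls[!is.na(cls$class_last), ]
  expect_equal(rowSums(ts$counts),
               table(factor(assessed$class0, levels = risk_class_levels))[
                 risk_class_levels],
               ignore_attr = TRUE)
  expect_equal(sum(ts$counts), ts$n_assessed)
})

test_that("classify_cohort uses the last non-missing follow-up HtTKV", {
  co <- tiny_cohort()
  cls <- classify_cohort(co)
  # patient B has a missing HtTKV at t = 1; last non-missing is t = 2
  expect_equal(cls$rate_last[cls$patient_id == "B"],
               estimated_growth_rate(880, 45 + 2))
})
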