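# Agreement and discrimination metrics.

test_that("bias and limits of agreement reproduce hand computations", {
  expect_equal(bias_and_loa(c(10, 20, 30), c(10, 20, 30)),
               list(bias = 0, loa_low = 0, loa_high = 0, sd_diff = 0))
  # diffs -2, 2, -3: mean -1, sd = sqrt(7)
  ba <- bias_and_loa(c(10, 20, 30), c(12, 18, 33))
  expect_equal(ba$bias, -1)
  expect_equal(ba$sd_diff, sqrt(7))
  expect_equal(ba$loa_low, -1 - 1.96 * sqrt(7))
  expect_equal(round(c(ba$loa_low, ba$loa_high), 3), c(-6.186, 4.186))
  # diffs 30, -30: sd = 30 * sqrt(2)
  ba2 <- bias_and_loa(c(100, 100), c(70, 130))
  expect_equal(ba2$bias, 0)
  expect_equal(round(ba2$loa_high, 2), 83.16)
  expect_error(bias_and_loa(1, 1), class = "adpkdval_insufficient_data")
})

test_that("P30 counts the 30% band inclusively", {
  expect_equal(p30(c(50, 80), c(50, 80)), 100)
  expect_equal(p30(rep(100, 4), c(129, 131, 71, 69)), 50)
  expect_equal(p30(100, 130), 100)  # boundary counts
  expect_equal(p30(100, 130.0001), 0)
  expect_error(p30(c(100, -1), c(90, 1)), class = "adpkdval_domain_error")
})

test_that("both R-squared variants match independent formula evaluations", {
  obs <- c(55, 72, 81, 94, 63, 70)
  pred <- c(58, 70, 85, 90, 60, 75)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, obs, "squared_pearson"), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 6)), 0)
  # independently coded formulas
  expect_equal(r_squared(obs, pred),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  expect_equal(r_squared(obs, pred, "squared_pearson"),
               (sum((obs - mean(obs)) * (pred - mean(pred))) /
                  sqrt(sum((obs - mean(obs))^2) *
                         sum((pred - mean(pred))^2)))^2,
               tolerance = 1e-12)
  expect_error(r_squared(rep(5, 3), 1:3), class = "adpkdval_domain_error")
})

test_that("AIC is -2 logLik + 2k and matches stats::AIC on a real fit", {
  expect_equal(aic(0, 1), 2)
  expect_equal(aic(-100, 5), 210)
  fit <- stats::lm(dist ~ speed, data = cars)
  ll <- logLik(fit)
  expect_equal(aic(as.numeric(ll), attr(ll, "df")), stats::AIC(fit),
               tolerance = 1e-6)
})

test_that("normal CRPS closed form matches its known values", {
  expect_equal(crps_normal(5, 0, 3), 2)  # degenerate point forecast
  expect_equal(crps_normal(1, 1, 1), 2 * dnorm(0) - 1 / sqrt(pi),
               tolerance = 1e-12)
  expect_equal(crps_normal(1, 1, 1), 0.2336950, tolerance = 1e-6)
  expect_equal(round(crps_normal(0, 1, 1), 5), 0.60244)
})

test_that("normal CRPS is a proper distance-like score", {
  expect_true(all(crps_normal(c(-3, 0, 2), c(0, 1, 4), 1) >= 0))
  expect_equal(crps_normal(1, 0, 1), 0)
  expect_gt(crps_normal(1, 1, 1), 0)  # zero only for sigma = 0 and y = mu
  # strictly increasing in |y - mu| for fixed sigma
  errs <- crps_normal(0, 2, seq(0, 10, by = 0.5))
  expect_true(all(diff(errs) > 0))
})

test_that("sample CRPS matches the enumerated pair formula", {
  expect_equal(crps_sample(rep(3, 10), 3), 0)
  expect_equal(crps_sample(c(0, 2), 1), 0.5)  # enumerate the 4 ordered pairs
  set.seed(4)
  x <- rnorm(60, 2, 3)
  y <- 1.3
  naive <- mean(abs(x - y)) - 0.5 * mean(abs(outer(x, x, "-")))
  expect_equal(crps_sample(x, y), naive, tolerance = 1e-12)
  expect_error(crps_sample(1, 1))
})

test_that("mean CRPS averages the per-pair closed form", {
  pr <- tibble::tibble(egfr_pred = c(50, 60, 70), pred_sd = c(0, 0, 0),
                       egfr_obs = c(50, 60, 70))
  expect_equal(mean_crps(pr), 0)
  sigma <- 3.7
  pr2 <- tibble::tibble(egfr_pred = c(50, 60), pred_sd = sigma,
                        egfr_obs = c(50, 60))
  expect_equal(mean_crps(pr2), sigma * (2 * dnorm(0) - 1 / sqrt(pi)),
               tolerance = 1e-12)
  # permutation invariance
  set.seed(5)
  pr3 <- tibble::tibble(egfr_pred = rnorm(20, 70, 10), pred_sd = runif(20, 1, 6),
                        egfr_obs = rnorm(20, 70, 10))
  i <- sample(20)
  expect_equal(mean_crps(pr3), mean_crps(pr3[i, ]))
  pr3$pred_sd[3] <- NA
  expect_error(mean_crps(pr3), "SD")
})

test_that("validation reports honour the LoA identity and carry both R2s", {
  set.seed(6)
  obs <- rnorm(50, 75, 12)
  pred <- obs + rnorm(50, 1, 5)
  rep <- validation_report(obs, pred, pred_sd = rep(5, 50), loglik = -120,
                           n_params = 12, model = "demo")
  d <- obs - pred
  expect_equal(rep$loa_low, rep$bias - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(rep$loa_high, rep$bias + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(rep$aic, 264)
  expect_true(rep$r2_squared_pearson >= 0 && rep$r2_squared_pearson <= 1)
  expect_equal(rep$correlation, cor(obs, pred))
  # joint permutation invariance of bias and P30
  i <- sample(50)
  expect_equal(p30(obs[i], pred[i]), rep$p30)
  expect_equal(mean(obs[i] - pred[i]), rep$bias)
})

test_that("the two R2 variants coincide for unbiased linear predictions", {
  # regression fitted values are unbiased and linear in the observations
  set.seed(8)
  x <- rnorm(80)
  obs <- 3 + 2 * x + rnorm(80)
  pred <- stats::fitted(stats::lm(obs ~ x))
  expect_equal(r_squared(obs, pred), r_squared(obs, pred, "squared_pearson"),
               tolerance = 1e-10)
})
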