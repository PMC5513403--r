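#' Bland-Altman bias and 95% limits of agreement
#'
#' Bias is the mean of (observed - predicted); the 95% limits of agreement
#' are bias +/- 1.96 times the sample standard deviation (n - 1 denominator)
#' of the differences. The multiplier 1.96 is used literally, not a
#' t-quantile.
#'
#' @param obs,pred Equal-length numeric vectors of observed and predicted
#'   eGFR (length >= 2).
#' @return Named list `bias`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bias_and_loa <- function(obs, pred) {
  check_pairs(obs, pred, min_n = 2)
  d <- obs - pred
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s)
}

#' P30 accuracy
#'
#' Percentage of predictions within 30% of the observed value, boundary
#' inclusive: `100 * mean(|pred - obs| <= 0.30 * obs)`.
#'
#' @inheritParams bias_and_loa
#' @return Percentage in \[0, 100\].
#' @export
p30 <- function(obs, pred) {
  check_pairs(obs, pred, min_n = 1)
  if (any(obs <= 0)) {
    abort_input("observed values must be positive for P30",
                "adpkdval_domain_error")
  }
  100 * mean(abs(pred - obs) <= 0.30 * obs)
}

#' R-squared between observed and predicted values
#'
#' Two variants: `one_minus_sse_sst` is
#' \eqn{1 - \sum(obs-pred)^2 / \sum(obs - \bar{obs})^2}, the fraction of
#' observed variance explained by the predictions as issued (can be
#' negative); `squared_pearson` is the squared Pearson correlation, blind to
#' calibration. They coincide for unbiased linear predictions, and reports
#' carry both because published values of "R-squared" do not always say
#' which was meant.
#'
#' @inheritParams bias_and_loa
#' @param variant `"one_minus_sse_sst"` (default) or `"squared_pearson"`.
#' @return Scalar R-squared.
#' @export
r_squared <- function(obs, pred,
                      variant = c("one_minus_sse_sst", "squared_pearson")) {
  variant <- match.arg(variant)
  check_pairs(obs, pred, min_n = 2)
  if (var(obs) == 0) {
    abort_input("R-squared undefined for constant observations",
                "adpkdval_domain_error")
  }
  if (variant == "one_minus_sse_sst") {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  } else {
    stats::cor(obs, pred)^2
  }
}

#' Akaike information criterion
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Number of estimated parameters (fixed effects plus
#'   variance components under ML), >= 1.
#' @return `-2 * loglik + 2 * n_params`.
#' @export
aic <- function(loglik, n_params) {
  assert_that(is_scalar_number(n_params) && n_params >= 1,
              "n_params must be >= 1")
  -2 * as.numeric(loglik) + 2 * n_params
}

#' Continuous ranked probability score of a normal forecast
#'
#' Closed form for a N(mu, sigma^2) predictive distribution and observation
#' y: \eqn{\sigma [ z(2\Phi(z)-1) + 2\phi(z) - 1/\sqrt{\pi} ]} with
#' \eqn{z = (y-\mu)/\sigma}. At `sigma = 0` it degenerates to the absolute
#' error `|y - mu|`. Lower is better; 0 only for a perfect point forecast.
#'
#' @param mu,sigma Mean and standard deviation (>= 0) of the forecast.
#' @param y Observed value.
#' @return CRPS on the scale of `y`. Vectorised.
#' @export
crps_normal <- function(mu, sigma, y) {
  if (any(sigma < 0)) {
    abort_input("sigma must be >= 0", "adpkdval_domain_error")
  }
  n <- max(length(mu), length(sigma), length(y))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); y <- rep_len(y, n)
  out <- abs(y - mu)
  pos <- sigma > 0
  if (any(pos)) {
    z <- (y[pos] - mu[pos]) / sigma[pos]
    out[pos] <- sigma[pos] *
      (z * (2 * pnorm(z) - 1) + 2 * dnorm(z) - 1 / sqrt(pi))
  }
  out
}

#' Empirical (sample-based) CRPS
#'
#' `mean|X - y| - 0.5 * mean|X - X'|`, the second average over all ordered
#' sample pairs, computed in O(n log n) via the sorted-sample identity.
#' Serves as the Monte-Carlo oracle for [crps_normal()].
#'
#' @param samples Numeric vector of >= 2 draws from the predictive
#'   distribution.
#' @param y Observed value.
#' @return Scalar CRPS.
#' @export
crps_sample <- function(samples, y) {
  n <- length(samples)
  assert_that(n >= 2, "crps_sample needs at least 2 samples")
  assert_that(is_scalar_number(y), "y must be a single number")
  xs <- sort(samples)
  # mean over n^2 ordered pairs of |X - X'| = (2/n^2) * sum_i (2i - n - 1) x_(i)
  mean_pair <- 2 * sum((2 * seq_len(n) - n - 1) * xs) / n^2
  mean(abs(samples - y)) - 0.5 * mean_pair
}

#' Mean CRPS over a prediction set
#'
#' Averages [crps_normal()] over matched prediction/observation pairs using
#' each prediction's marginal predictive standard deviation.
#'
#' @param predictions Tibble with `egfr_pred` and `pred_sd` columns (as from
#'   [predict_cohort()]).
#' @param observations Numeric vector of observed eGFR; defaults to the
#'   `egfr_obs` column of `predictions`.
#' @return Scalar mean CRPS.
#' @export
mean_crps <- function(predictions, observations = predictions$egfr_obs) {
  if (is.null(predictions$pred_sd) || any(is.na(predictions$pred_sd))) {
    abort_input(paste("predictions carry no predictive SD; use a model",
                      "providing pred_sd (marginal mixed-model predictions)"))
  }
  check_pairs(observations, predictions$egfr_pred, min_n = 1)
  mean(crps_normal(predictions$egfr_pred, predictions$pred_sd, observations))
}

check_pairs <- function(obs, pred, min_n) {
  if (length(obs) != length(pred)) {
    abort_input("obs and pred must have equal length")
  }
  if (length(obs) < min_n || any(!is.finite(obs)) || any(!is.finite(pred))) {
    abort_input(sprintf("need >= %d finite obs/pred pairs", min_n),
                "adpkdval_insufficient_data")
  }
  invisible(TRUE)
}

#' Assemble a validation report
#'
#' The per-model summary used throughout the package: number of
#' observations, both R-squared variants plus the configurable headline,
#' Bland-Altman bias and 95% limits of agreement, Pearson correlation, P30,
#' and optionally AIC and mean CRPS.
#'
#' @inheritParams bias_and_loa
#' @param pred_sd Optional per-prediction marginal SD (enables CRPS).
#' @param loglik,n_params Optional log-likelihood and parameter count
#'   (enables AIC; the count includes fixed effects plus variance
#'   components under ML).
#' @param headline_r2 Which variant fills the `r2` column.
#' @param model Label for the model row.
#' @return One-row tibble of class `validation_report`.
#' @export
validation_report <- function(obs, pred, pred_sd = NULL, loglik = NULL,
                              n_params = NULL,
                              headline_r2 = c("one_minus_sse_sst",
                                              "squared_pearson"),
                              model = NA_character_) {
  headline_r2 <- match.arg(headline_r2)
  check_pairs(obs, pred, min_n = 2)
  ba <- bias_and_loa(obs, pred)
  r2a <- r_squared(obs, pred, "one_minus_sse_sst")
  r2b <- r_squared(obs, pred, "squared_pearson")
  rep <- tibble(
    model = model,
    n_obs = length(obs),
    r2 = if (headline_r2 == "one_minus_sse_sst") r2a else r2b,
    r2_one_minus_sse_sst = r2a,
    r2_squared_pearson = r2b,
    bias = ba$bias,
    loa_low = ba$loa_low,
    loa_high = ba$loa_high,
    correlation = stats::cor(obs, pred),
    p30 = p30(obs, pred),
    aic = if (!is.null(loglik)) aic(loglik, n_params) else NA_real_,
    crps = if (!is.null(pred_sd))
      mean_crps(tibble(egfr_pred = pred, pred_sd = pred_sd), obs) else
      NA_real_)
  class(rep) <- c("validation_report", class(rep))
  rep
}
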