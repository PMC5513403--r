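#' Mayo-style risk subclasses
#'
#' The five ordinal subclasses 1A-1E are defined by the theoretical yearly
#' percentage kidney growth implied by a single age/HtTKV pair, with
#' boundaries at 1.5, 3.0, 4.5 and 6.0 %/yr. Boundaries are left-closed into
#' the higher class: a rate of exactly 1.5%/yr is 1B.
#'
#' @format `risk_class_levels` is the ordered character vector
#'   `c("1A","1B","1C","1D","1E")`; `risk_class_breaks` the rate thresholds
#'   (fraction/yr) separating them.
#' @name risk_classes
NULL

#' @rdname risk_classes
#' @export
risk_class_levels <- c("1A", "1B", "1C", "1D", "1E")

#' @rdname risk_classes
#' @export
risk_class_breaks <- c(0.015, 0.030, 0.045, 0.060)

#' Estimated yearly kidney growth rate from one age/HtTKV pair
#'
#' Solves `httkv_birth * (1 + r)^age = httkv` for `r`: the constant yearly
#' growth rate that would carry a theoretical at-birth HtTKV to the observed
#' value by the observed age.
#'
#' @param httkv HtTKV in ml/m, positive.
#' @param age Age in years, positive.
#' @param httkv_birth Theoretical HtTKV at age zero (default 150 ml/m),
#'   exposed as a parameter.
#' @return Estimated growth rate as a fraction per year. Vectorised.
#' @examples
#' estimated_growth_rate(600, 40)  # ~0.0353, class 1C
#' @export
estimated_growth_rate <- function(httkv, age, httkv_birth = 150) {
  if (any(!is.finite(httkv)) || any(httkv <= 0)) {
    abort_input("httkv must be positive", "adpkdval_domain_error")
  }
  if (any(!is.finite(age)) || any(age <= 0)) {
    abort_input("age must be positive", "adpkdval_domain_error")
  }
  assert_that(all(httkv_birth > 0), "httkv_birth must be positive")
  (httkv / httkv_birth)^(1 / age) - 1
}

#' Assign a risk subclass from a growth rate
#'
#' @param rate Yearly growth rate (fraction/yr), > -1. Boundaries belong to
#'   the upper class (0.015 maps to 1B).
#' @return Ordered factor with levels 1A < 1B < 1C < 1D < 1E.
#' @export
assign_class <- function(rate) {
  if (any(!is.finite(rate)) || any(rate <= -1)) {
    abort_input("rate must be a finite number > -1", "adpkdval_domain_error")
  }
  idx <- findInterval(rate, risk_class_breaks) + 1L  # left-closed boundaries
  factor(risk_class_levels[idx], levels = risk_class_levels, ordered = TRUE)
}

#' Age-dependent HtTKV class boundary
#'
#' The HtTKV limit at a given age for a growth-rate threshold:
#' `httkv_birth * (1 + rate_threshold)^age`, the inverse of
#' [estimated_growth_rate()] at the threshold.
#'
#' @param age Age in years, positive.
#' @param rate_threshold Growth-rate threshold (fraction/yr).
#' @inheritParams estimated_growth_rate
#' @return HtTKV in ml/m. Vectorised.
#' @export
class_boundary_httkv <- function(age, rate_threshold, httkv_birth = 150) {
  if (any(!is.finite(age)) || any(age <= 0)) {
    abort_input("age must be positive", "adpkdval_domain_error")
  }
  httkv_birth * (1 + rate_threshold)^age
}

#' Class-boundary curves on an age grid
#'
#' @param ages Numeric vector of ages (years).
#' @param thresholds Growth-rate thresholds; defaults to the four class
#'   boundaries.
#' @inheritParams estimated_growth_rate
#' @return Tibble `age`, `threshold`, `httkv_limit` suitable for plotting
#'   the classification chart.
#' @export
boundary_table <- function(ages = 18:80, thresholds = risk_class_breaks,
                           httkv_birth = 150) {
  grid <- expand.grid(age = ages, threshold = thresholds)
  tibble(age = grid$age, threshold = grid$threshold,
         httkv_limit = class_boundary_httkv(grid$age, grid$threshold,
                                            httkv_birth))
}

#' Per-patient baseline and final risk classes
#'
#' Baseline class from (`httkv0`, `age0`); final class from the last
#' non-missing follow-up HtTKV and the age at that visit (`age0 + t`).
#' Patients with no non-missing follow-up HtTKV have `NA` final class.
#'
#' @param cohort A [long_cohort()].
#' @inheritParams estimated_growth_rate
#' @return Tibble `patient_id`, `rate0`, `class0`, `rate_last`, `class_last`.
#' @export
classify_cohort <- function(cohort, httkv_birth = 150) {
  stopifnot(inherits(cohort, "adpkd_long_cohort"))
  b <- cohort$baselines
  out <- tibble(
    patient_id = b$patient_id,
    rate0 = estimated_growth_rate(b$httkv0, b$age0, httkv_birth),
    class0 = assign_class(estimated_growth_rate(b$httkv0, b$age0,
                                                httkv_birth)),
    rate_last = NA_real_,
    class_last = factor(NA, levels = risk_class_levels, ordered = TRUE))
  v <- cohort$visits[!is.na(cohort$visits$httkv), , drop = FALSE]
  if (nrow(v) > 0) {
    v <- v[order(v$patient_id, v$t_years), , drop = FALSE]
    last <- v[!duplicated(v$patient_id, fromLast = TRUE), , drop = FALSE]
    i <- match(last$patient_id, out$patient_id)
    age_last <- b$age0[i] + last$t_years
    out$rate_last[i] <- estimated_growth_rate(last$httkv, age_last,
                                              httkv_birth)
    out$class_last[i] <- assign_class(out$rate_last[i])
  }
  out
}

#' Summarise risk-class transitions over follow-up
#'
#' Cross-tabulates baseline against final risk class. Patients without any
#' non-missing follow-up HtTKV are excluded from `n_assessed`. Progression
#' means moving to a more severe class (above the diagonal), regression to a
#' milder one.
#'
#' @inheritParams classify_cohort
#' @return A `transition_summary`: list with the 5x5 `counts` matrix
#'   (baseline class in rows, final class in columns), `n_assessed`,
#'   `pct_progressed` and `pct_regressed` (both `NA` when `n_assessed` is 0).
#' @export
transition_summary <- function(cohort, httkv_birth = 150) {
  cls <- classify_cohort(cohort, httkv_birth)
  assessed <- cls[!is.na(cls$class_last), , drop = FALSE]
  counts <- table(factor(assessed$class0, levels = risk_class_levels),
                  factor(assessed$class_last, levels = risk_class_levels))
  counts <- unclass(matrix(counts, 5, 5,
                           dimnames = list(baseline = risk_class_levels,
                                           final = risk_class_levels)))
  n <- nrow(assessed)
  structure(list(
    counts = counts,
    n_assessed = n,
    pct_progressed = if (n > 0) 100 * sum(counts[upper.tri(counts)]) / n else
      NA_real_,
    pct_regressed = if (n > 0) 100 * sum(counts[lower.tri(counts)]) / n else
      NA_real_),
    class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("Risk-class transitions: %d patients assessed\n", x$n_assessed))
  print(x$counts)
  cat(sprintf("  progressed %.1f%%, regressed %.1f%%\n",
              x$pct_progressed, x$pct_regressed))
  invisible(x)
}
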