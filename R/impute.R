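#' Multiple imputation of missing follow-up HtTKV
#'
#' Data-augmentation MCMC under a joint multivariate-normal model of
#' (log2 HtTKV, years of follow-up, baseline age, sex, observed eGFR,
#' baseline eGFR) over participant-visits. The sampler alternates a
#' parameter draw from the normal-inverse-Wishart posterior (Jeffreys
#' prior) given the completed data with a conditional-normal draw of the
#' missing log2 HtTKV values given the observed variables in their row.
#' Imputation is done on the log2 scale (the model's scale, where
#' normality is most plausible) and back-transformed, so imputed HtTKV is
#' always positive. `m` completed cohorts are taken at thinned intervals
#' after burn-in. A cohort with nothing missing returns `m` identical
#' copies without running the sampler.
#'
#' Only follow-up HtTKV may be missing: missingness in the outcome or any
#' design covariate raises an unsupported-pattern error (baseline HtTKV
#' can never be missing in a valid cohort).
#'
#' @param cohort A [long_cohort()].
#' @param m Number of imputed data sets (default 30).
#' @param n_burnin Burn-in iterations before the first saved set.
#' @param n_thin Iterations between saved sets.
#' @param seed Optional seed; the whole set is reproducible under it.
#' @return An `imputation_set`: list with `m`, `cohorts` (list of `m`
#'   completed [long_cohort()]s), `seed`, `n_burnin`, `n_thin`,
#'   `imputation_model_vars`, and `missing_rows` (visit-row indices that
#'   were imputed).
#' @export
impute_httkv <- function(cohort, m = 30, n_burnin = 500, n_thin = 100,
                         seed = NULL) {
  stopifnot(inherits(cohort, "adpkd_long_cohort"))
  assert_that(is_scalar_number(m) && m >= 1, "m must be >= 1")
  assert_that(is_scalar_number(n_burnin) && n_burnin >= 0,
              "n_burnin must be >= 0")
  assert_that(is_scalar_number(n_thin) && n_thin >= 1, "n_thin must be >= 1")
  vars <- c("log2_httkv", "t_years", "age0", "sex", "egfr_obs", "egfr0")

  v <- dplyr::left_join(cohort$visits, cohort$baselines, by = "patient_id")
  Z <- cbind(log2_httkv = log2(v$httkv),
             t_years = v$t_years,
             age0 = v$age0,
             sex = as.numeric(v$sex == "female"),
             egfr_obs = v$egfr_obs,
             egfr0 = v$egfr0)
  if (any(is.na(Z[, -1]))) {
    abort_input(paste("missingness outside follow-up HtTKV is not supported",
                      "by this imputation model"),
                class = "adpkdval_unsupported_pattern")
  }
  miss <- which(is.na(Z[, 1]))
  base <- list(m = as.integer(m), seed = seed,
               n_burnin = as.integer(n_burnin), n_thin = as.integer(n_thin),
               imputation_model_vars = vars, missing_rows = miss)
  if (length(miss) == 0) {
    return(structure(c(base, list(cohorts = rep(list(cohort), m))),
                     class = "imputation_set"))
  }
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(Z); d <- ncol(Z)
  Z[miss, 1] <- mean(Z[-miss, 1])  # initialise at the observed mean
  obs_cols <- 2:d
  Zobs <- Z[miss, obs_cols, drop = FALSE]
  cohorts <- vector("list", m)
  total <- n_burnin + m * n_thin
  saved <- 0L
  for (it in seq_len(total)) {
    # (Sigma, mu) | completed data: Jeffreys-prior NIW posterior.
    xbar <- colMeans(Z)
    S <- crossprod(sweep(Z, 2, xbar))
    Sigma <- chol2inv(chol(drop(rWishart(1, n - 1, chol2inv(chol(S))))))
    mu <- drop(xbar + t(chol(Sigma / n)) %*% rnorm(d))
    # missing log2 HtTKV | observed row variables: conditional normal.
    b <- solve(Sigma[obs_cols, obs_cols], Sigma[obs_cols, 1])
    cvar <- Sigma[1, 1] - drop(Sigma[1, obs_cols] %*% b)
    cmean <- mu[1] + drop(sweep(Zobs, 2, mu[obs_cols]) %*% b)
    Z[miss, 1] <- cmean + rnorm(length(miss), 0, sqrt(max(cvar, 0)))
    if (it > n_burnin && (it - n_burnin) %% n_thin == 0) {
      saved <- saved + 1L
      filled <- cohort
      filled$visits$httkv[miss] <- 2^Z[miss, 1]
      cohorts[[saved]] <- filled
    }
  }
  structure(c(base, list(cohorts = cohorts)), class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf(paste0("Imputation set: m = %d completed cohorts, %d imputed ",
                     "HtTKV cells\n  burn-in %d, thinning %d, variables: %s\n"),
              x$m, length(x$missing_rows), x$n_burnin, x$n_thin,
              paste(x$imputation_model_vars, collapse = ", ")))
  invisible(x)
}

#' Pool results across imputations
#'
#' Scalar performance metrics ([validation_report()] rows) are pooled by
#' their mean across imputations, with the between-imputation variance of
#' each metric recorded. Coefficient sets are pooled by Rubin's rules:
#' pooled estimate = mean; between-imputation variance
#' \eqn{B = \sum_i (\beta_i - \bar\beta)^2 / (m - 1)}; total variance
#' \eqn{T = W + (1 + 1/m) B} where `W` is the mean within-imputation
#' variance (0 when no within-imputation variances are supplied).
#'
#' @param reports A list of `m >= 2` [validation_report()] rows, or of
#'   `egfr_model_coefficients` objects / named coefficient vectors of
#'   identical shape.
#' @param within_variances Optional list of named within-imputation variance
#'   vectors matching the coefficient sets.
#' @return For reports: a pooled `validation_report` with attributes `m` and
#'   `between_variance`. For coefficients: list `m`, `beta`, `between_var`,
#'   `within_var`, `total_var`.
#' @export
pool_reports <- function(reports, within_variances = NULL) {
  assert_that(is.list(reports) && length(reports) >= 2,
              "need m >= 2 results to pool")
  if (inherits(reports[[1]], "validation_report")) {
    cols <- vapply(reports, nrow, 1L)
    assert_that(all(cols == 1L), "each report must be a one-row summary")
    nm <- names(reports[[1]])
    assert_that(all(vapply(reports, function(r) identical(names(r), nm),
                           TRUE)),
                "reports have mismatched shapes")
    stacked <- dplyr::bind_rows(reports)
    pooled <- stacked[1, ]
    num <- vapply(stacked, is.numeric, TRUE)
    pooled[, num] <- as.list(colMeans(stacked[, num, drop = FALSE]))
    attr(pooled, "m") <- length(reports)
    attr(pooled, "between_variance") <-
      vapply(stacked[, num, drop = FALSE], var, numeric(1))
    return(pooled)
  }
  betas <- lapply(reports, function(r) {
    if (inherits(r, "egfr_model_coefficients")) r$beta else r
  })
  nm <- names(betas[[1]])
  assert_that(all(vapply(betas, function(b) identical(names(b), nm), TRUE)),
              "coefficient sets have mismatched terms")
  M <- do.call(rbind, betas)
  m <- nrow(M)
  B <- apply(M, 2, var)
  W <- if (is.null(within_variances)) setNames(numeric(length(nm)), nm) else
    colMeans(do.call(rbind, within_variances))
  list(m = m, beta = colMeans(M), between_var = B, within_var = W,
       total_var = W + (1 + 1 / m) * B)
}
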