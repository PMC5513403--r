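#' Patient-level k-fold assignment
#'
#' Partitions patients (not visits) into k folds of sizes differing by at
#' most one, so that all visits of a patient share a fold.
#'
#' @param cohort A [long_cohort()].
#' @param k Number of folds, >= 2 and at most the number of patients.
#' @param seed Optional seed for the shuffle.
#' @return Tibble `patient_id`, `fold`.
#' @export
make_folds <- function(cohort, k = 5, seed = NULL) {
  stopifnot(inherits(cohort, "adpkd_long_cohort"))
  ids <- cohort$baselines$patient_id
  n <- length(ids)
  assert_that(is_scalar_number(k) && k >= 2, "k must be >= 2")
  if (n < k) abort_input("fewer patients than folds")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(ids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  out <- tibble(patient_id = perm, fold = rep(seq_len(k), times = sizes))
  out[order(out$patient_id), ]
}

#' Cross-validated validation report for an updated model
#'
#' Five-fold (by default) patient-level cross-validation of a partial
#' update: for each fold the HtTKV coefficient is refit on the training
#' folds via [partial_update()] and predictions are made on the held-out
#' patients; metrics are pooled over all held-out predictions. AIC is not a
#' cross-validated quantity and is reported as `NA` here (compute it from a
#' full-data [partial_update()] if needed).
#'
#' @inheritParams partial_update
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param headline_r2 Passed to [validation_report()].
#' @param model Row label for the report.
#' @return A [validation_report()]; attribute `cv_predictions` holds the
#'   pooled held-out predictions.
#' @export
cross_validated_report <- function(cohort, coeffs,
                                   update_mode = c("model1_two_tkv",
                                                   "model2_time_varying"),
                                   with_interaction = FALSE,
                                   replace_baseline = FALSE,
                                   k = 5, seed = NULL,
                                   headline_r2 = "one_minus_sse_sst",
                                   model = NA_character_) {
  update_mode <- match.arg(update_mode)
  folds <- make_folds(cohort, k, seed)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- folds$patient_id[folds$fold == f]
    train <- subset_cohort(cohort, setdiff(folds$patient_id, test_ids))
    upd <- partial_update(coeffs, train, update_mode,
                          with_interaction = with_interaction,
                          replace_baseline = replace_baseline)
    preds[[f]] <- predict_cohort(upd, subset_cohort(cohort, test_ids))
  }
  pooled <- dplyr::bind_rows(preds)
  rep <- validation_report(pooled$egfr_obs, pooled$egfr_pred,
                           pred_sd = pooled$pred_sd,
                           headline_r2 = headline_r2, model = model)
  attr(rep, "cv_predictions") <- pooled
  rep
}
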