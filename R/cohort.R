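#' Long-format longitudinal ADPKD cohort
#'
#' A cohort is a pair of tibbles: one row per patient of baseline (time-zero)
#' covariates, and one row per follow-up visit. Validity rules: every visit's
#' `patient_id` exists in the baselines, every patient has at least one
#' follow-up visit, visit times are strictly increasing within patient,
#' baselines satisfy the eligibility rules (age over 18 years, baseline eGFR
#' over 30 ml/min/1.73m^2), and HtTKV/eGFR values are positive where present.
#'
#' @param baselines Tibble with columns `patient_id`, `sex`
#'   (`"female"`/`"male"`), `age0` (years), `height_m`, `creatinine0`
#'   (mg/dL, may be `NA`), `egfr0`, `httkv0` (ml/m). A `risk_class0` column
#'   is added (from `httkv0` and `age0`) if absent. Synthetic-only truth
#'   columns (prefix `true_`) are allowed and never serialised.
#' @param visits Tibble with columns `patient_id`, `t_years` (> 0),
#'   `egfr_obs`, `httkv` (ml/m, `NA` = missing).
#' @return An object of class `adpkd_long_cohort`.
#' @export
long_cohort <- function(baselines, visits) {
  baselines <- as_tibble(baselines)
  visits <- as_tibble(visits)
  need_b <- c("patient_id", "sex", "age0", "height_m", "creatinine0",
              "egfr0", "httkv0")
  need_v <- c("patient_id", "t_years", "egfr_obs", "httkv")
  assert_that(all(need_b %in% names(baselines)),
              paste("baselines must have columns:",
                    paste(setdiff(need_b, names(baselines)), collapse = ", ")))
  assert_that(all(need_v %in% names(visits)),
              paste("visits must have columns:",
                    paste(setdiff(need_v, names(visits)), collapse = ", ")))
  assert_that(!anyDuplicated(baselines$patient_id),
              "duplicate patient_id in baselines")
  if (nrow(baselines) > 0) {
    assert_that(all(baselines$age0 > 18),
                "eligibility violated: age0 must exceed 18 years")
    assert_that(all(baselines$egfr0 > 30),
                "eligibility violated: egfr0 must exceed 30 ml/min/1.73m2")
    assert_that(all(baselines$height_m > 0), "height must be positive")
    assert_that(all(baselines$httkv0 > 0), "httkv0 must be positive")
    match_sex(baselines$sex)
  }
  if (!"risk_class0" %in% names(baselines)) {
    baselines$risk_class0 <- if (nrow(baselines) == 0) character(0) else
      assign_class(estimated_growth_rate(baselines$httkv0, baselines$age0))
  }
  if (nrow(visits) > 0) {
    assert_that(all(visits$patient_id %in% baselines$patient_id),
                "visit patient_id absent from baselines")
    assert_that(all(visits$t_years > 0),
                "follow-up visit times must be positive")
    assert_that(all(visits$egfr_obs > 0, na.rm = TRUE),
                "egfr_obs must be positive when present")
    assert_that(all(visits$httkv > 0, na.rm = TRUE),
                "httkv must be positive when present")
    visits <- visits[order(visits$patient_id, visits$t_years), , drop = FALSE]
    assert_that(all(unlist(tapply(visits$t_years, visits$patient_id,
                                  function(tt) diff(c(0, tt)) > 0))),
                "visit times must be strictly increasing within patient")
  }
  if (nrow(baselines) > 0) {
    assert_that(all(baselines$patient_id %in% visits$patient_id),
                "every patient needs at least one follow-up visit")
  }
  structure(list(baselines = baselines, visits = visits),
            class = "adpkd_long_cohort")
}

#' @export
print.adpkd_long_cohort <- function(x, ...) {
  cat(sprintf("ADPKD long cohort: %d patients, %d follow-up visits\n",
              nrow(x$baselines), nrow(x$visits)))
  if (nrow(x$visits) > 0) {
    cat(sprintf("  follow-up %.2f-%.2f y; HtTKV missing at %d/%d visits\n",
                min(x$visits$t_years), max(x$visits$t_years),
                sum(is.na(x$visits$httkv)), nrow(x$visits)))
  }
  invisible(x)
}

#' Restrict a cohort to a subset of patients
#'
#' @param cohort A [long_cohort()].
#' @param patient_ids Character vector of patient ids to keep.
#' @return A [long_cohort()] with only those patients.
#' @export
subset_cohort <- function(cohort, patient_ids) {
  stopifnot(inherits(cohort, "adpkd_long_cohort"))
  long_cohort(cohort$baselines[cohort$baselines$patient_id %in% patient_ids, ],
              cohort$visits[cohort$visits$patient_id %in% patient_ids, ])
}

cohort_csv_header <- c("patient_id", "sex", "age0", "height_m", "creatinine0",
                       "egfr0", "httkv0", "t_years", "egfr_obs", "httkv")

#' Write a cohort to CSV
#'
#' One row per follow-up visit with the baseline columns repeated; fixed
#' header `patient_id,sex,age0,height_m,creatinine0,egfr0,httkv0,t_years,
#' egfr_obs,httkv`. Missing HtTKV is encoded as an empty field. Synthetic
#' truth columns (`true_*`) and the recomputable `risk_class0` are not
#' serialised.
#'
#' @param cohort A [long_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "adpkd_long_cohort"))
  b <- cohort$baselines[, c("patient_id", "sex", "age0", "height_m",
                            "creatinine0", "egfr0", "httkv0")]
  df <- dplyr::left_join(cohort$visits, b, by = "patient_id")
  df <- df[order(df$patient_id, df$t_years), cohort_csv_header]
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Strict inverse of [write_cohort()]: the header must match the declared
#' column set exactly, and malformed fields raise a line-numbered parse
#' error.
#'
#' @param path CSV file path.
#' @return A [long_cohort()].
#' @export
read_cohort <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  if (!identical(header, cohort_csv_header)) {
    bad <- c(setdiff(header, cohort_csv_header),
             setdiff(cohort_csv_header, header))
    abort_input(paste0("cohort CSV header mismatch; offending column(s): ",
                       paste(unique(bad), collapse = ", ")),
                class = "adpkdval_parse_error")
  }
  df <- readr::read_csv(
    path, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      sex = readr::col_character(),
      .default = readr::col_double()
    ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort_input(sprintf("malformed cohort CSV at line %d, column %d: %s",
                        probs$row[1], probs$col[1], probs$expected[1]),
                class = "adpkdval_parse_error")
  }
  b <- unique(df[, c("patient_id", "sex", "age0", "height_m", "creatinine0",
                     "egfr0", "httkv0")])
  if (anyDuplicated(b$patient_id)) {
    abort_input("inconsistent repeated baseline columns for a patient_id",
                class = "adpkdval_parse_error")
  }
  long_cohort(b, df[, c("patient_id", "t_years", "egfr_obs", "httkv")])
}
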