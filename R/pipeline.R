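#' Configuration for a full validation study run
#'
#' Bundles every choice [run_study()] needs: the development and validation
#' cohort generators (or a path to a cohort CSV for the validation side),
#' which model modes to validate with frozen coefficients, which partial
#' updates to evaluate, multiple-imputation and cross-validation settings,
#' and one master seed from which every random sub-stream derives.
#'
#' By default the development cohort emulates a Mayo-like development
#' sample (n = 376) and the validation cohort a Swiss-like external sample
#' (n = 214) whose generating truth carries a shifted HtTKV coefficient —
#' see [swiss_truth_coefficients()] — so that coefficient updating has a
#' real miscalibration to correct.
#'
#' @param master_seed Integer master seed.
#' @param n_development,n_validation Cohort sizes for the default
#'   generators (ignored when explicit configs are given).
#' @param development_config,validation_config Optional
#'   [generator_config()]s; their seeds are overridden by seeds derived
#'   from `master_seed`.
#' @param validation_cohort_path Optional path to a cohort CSV to validate
#'   on instead of generating one.
#' @param model_modes Subset of `c("validation_risk_class",
#'   "validation_tkv")` rows to produce, given as model modes
#'   `c("risk_class", "continuous_httkv")`. At least one.
#' @param updates Data frame with columns `update_mode` and
#'   `with_interaction` defining the updated-model rows, in Table order;
#'   `NULL` for none. Default: models 1 and 2, each without and with the
#'   HtTKV-by-years interaction.
#' @param mi Run multiple imputation for the updated models when follow-up
#'   HtTKV is missing.
#' @param m_imputations Number of imputed data sets (default 30).
#' @param cv_k Cross-validation folds for the updated models (>= 2).
#' @param use_truth_as_development Use the validation generator's true
#'   coefficients as the frozen external model instead of fitting a
#'   development cohort (closure testing; restricts modes to
#'   `continuous_httkv`).
#' @param output_dir Directory for the report bundle files; `NULL` to skip
#'   writing.
#' @param quiet Suppress per-stage log lines.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(master_seed = 1L,
                            n_development = 376,
                            n_validation = 214,
                            development_config = NULL,
                            validation_config = NULL,
                            validation_cohort_path = NULL,
                            model_modes = c("risk_class", "continuous_httkv"),
                            updates = default_update_grid(),
                            mi = TRUE,
                            m_imputations = 30,
                            cv_k = 5,
                            use_truth_as_development = FALSE,
                            output_dir = NULL,
                            quiet = FALSE) {
  assert_that(length(model_modes) >= 1 &&
                all(model_modes %in% c("risk_class", "continuous_httkv")),
              "model_modes must name at least one supported mode")
  if (!is.null(updates) && nrow(updates) > 0) {
    assert_that(is_scalar_number(cv_k) && cv_k >= 2,
                "cv_k must be >= 2 when updates are requested")
    assert_that("continuous_httkv" %in% model_modes || use_truth_as_development,
                "updates require the continuous_httkv mode")
  }
  if (use_truth_as_development) model_modes <- "continuous_httkv"
  if (is.null(development_config)) {
    development_config <- mayo_generator_config(n_patients = n_development)
  }
  if (is.null(validation_config)) {
    validation_config <- generator_config(n_patients = n_validation)
  }
  structure(list(master_seed = as.integer(master_seed),
                 development_config = development_config,
                 validation_config = validation_config,
                 validation_cohort_path = validation_cohort_path,
                 model_modes = model_modes, updates = updates,
                 mi = isTRUE(mi), m_imputations = m_imputations,
                 cv_k = cv_k,
                 use_truth_as_development = isTRUE(use_truth_as_development),
                 output_dir = output_dir, quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_update_grid <- function() {
  data.frame(update_mode = rep(c("model1_two_tkv", "model2_time_varying"),
                               each = 2),
             with_interaction = rep(c(FALSE, TRUE), 2),
             label = c("updated_model1", "updated_model1_interaction",
                       "updated_model2", "updated_model2_interaction"))
}

#' Run the full external-validation study
#'
#' End-to-end replica of the validation workflow: generate (or load) the
#' validation cohort, fit the development model(s) on a freshly generated
#' development cohort (or take the generating truth as the external model),
#' validate the frozen coefficients, summarise risk-class transitions,
#' multiply impute missing follow-up HtTKV, evaluate each requested partial
#' update by patient-level cross-validation (metrics pooled across
#' imputations; AIC from full-data updates), and assemble a report
#' table with one row per model in the order: frozen risk-class model,
#' frozen HtTKV model, updated model 1 without/with interaction, updated
#' model 2 without/with interaction. The frozen risk-class row reports no
#' AIC/CRPS (no refit likelihood and no accepted predictive distribution
#' convention for that model).
#'
#' Everything derives deterministically from `master_seed`: rerunning the
#' same configuration reproduces the report bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a bundle list: `table2` (the report tibble),
#'   `coefficients` (per-mode frozen fits), `updated_coefficients`,
#'   `transitions`, `predictions` (per-model plot data), `manifest`.
#'   When `config$output_dir` is set the bundle is also written there via
#'   [save_report()].
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!config$quiet) message(sprintf(...))
  seed_dev <- derive_seed(config$master_seed, 1)
  seed_val <- derive_seed(config$master_seed, 2)
  seed_mi <- derive_seed(config$master_seed, 3)
  seed_cv <- derive_seed(config$master_seed, 4)

  dev_cfg <- config$development_config
  dev_cfg$seed <- seed_dev
  val_cfg <- config$validation_config
  val_cfg$seed <- seed_val
  if (!is.null(config$validation_cohort_path)) {
    val_cohort <- load_cohort(config$validation_cohort_path)
    say("stage=load_validation n=%d", nrow(val_cohort$baselines))
  } else {
    val_cohort <- generate_cohort(val_cfg)
    say("stage=generate_validation seed=%d n=%d", seed_val,
        nrow(val_cohort$baselines))
  }

  coefficients <- list()
  reports <- list()
  predictions <- list()
  dev_cohort <- NULL
  if (config$use_truth_as_development) {
    coefficients$continuous_httkv <- val_cfg$egfr_model_truth
    say("stage=development model=truth")
  } else {
    dev_cohort <- generate_cohort(dev_cfg)
    say("stage=generate_development seed=%d n=%d", seed_dev,
        nrow(dev_cohort$baselines))
    for (mode in config$model_modes) {
      coefficients[[mode]] <- fit_development_model(dev_cohort, mode)
      say("stage=fit_development mode=%s loglik=%.2f", mode,
          attr(coefficients[[mode]], "loglik"))
    }
  }

  row_order <- c()
  for (mode in intersect(c("risk_class", "continuous_httkv"),
                         config$model_modes)) {
    label <- if (mode == "risk_class") "validation_risk_class" else
      "validation_tkv"
    cf <- coefficients[[mode]]
    pr <- predict_cohort(cf, val_cohort)
    if (mode == "risk_class") {
      reports[[label]] <- validation_report(pr$egfr_obs, pr$egfr_pred,
                                            model = label)
    } else {
      ll <- marginal_loglik(cf, val_cohort)
      reports[[label]] <- validation_report(
        pr$egfr_obs, pr$egfr_pred, pred_sd = pr$pred_sd,
        loglik = ll, n_params = length(cf$beta) + 2, model = label)
    }
    predictions[[label]] <- pr
    row_order <- c(row_order, label)
    say("stage=validate model=%s n=%d", label, nrow(pr))
  }

  transitions <- transition_summary(val_cohort)
  say("stage=transitions n_assessed=%d progressed=%.1f%%",
      transitions$n_assessed, transitions$pct_progressed)

  updated_coefficients <- list()
  if (!is.null(config$updates) && nrow(config$updates) > 0) {
    frozen <- coefficients$continuous_httkv
    any_missing <- anyNA(val_cohort$visits$httkv)
    completed <- if (config$mi && any_missing) {
      imp <- impute_httkv(val_cohort, m = config$m_imputations,
                          seed = seed_mi)
      say("stage=impute m=%d cells=%d", imp$m, length(imp$missing_rows))
      imp$cohorts
    } else {
      list(val_cohort)
    }
    for (i in seq_len(nrow(config$updates))) {
      u <- config$updates[i, ]
      per_imp <- lapply(seq_along(completed), function(j) {
        cv <- cross_validated_report(
          completed[[j]], frozen, u$update_mode,
          with_interaction = u$with_interaction,
          k = config$cv_k, seed = seed_cv, model = u$label)
        full <- partial_update(frozen, completed[[j]], u$update_mode,
                               with_interaction = u$with_interaction)
        cv$aic <- aic(attr(full, "loglik"), attr(full, "n_params"))
        list(cv = cv, full = full)
      })
      cvs <- lapply(per_imp, `[[`, "cv")
      reports[[u$label]] <- if (length(cvs) > 1) pool_reports(cvs) else
        cvs[[1]]
      updated_coefficients[[u$label]] <-
        if (length(per_imp) > 1)
          pool_reports(lapply(per_imp, `[[`, "full")) else
          per_imp[[1]]$full
      predictions[[u$label]] <- attr(cvs[[1]], "cv_predictions")
      row_order <- c(row_order, u$label)
      say("stage=update model=%s crps=%.2f", u$label,
          reports[[u$label]]$crps)
    }
  }

  table2 <- dplyr::bind_rows(reports[row_order])
  manifest <- list(
    master_seed = config$master_seed,
    seeds = list(development = seed_dev, validation = seed_val,
                 imputation = seed_mi, cross_validation = seed_cv),
    n_development = if (!is.null(dev_cohort)) nrow(dev_cohort$baselines) else
      0L,
    n_validation = nrow(val_cohort$baselines),
    n_validation_visits = nrow(val_cohort$visits),
    model_rows = row_order,
    mi = config$mi, m_imputations = config$m_imputations,
    cv_k = config$cv_k,
    use_truth_as_development = config$use_truth_as_development,
    plot_data_imputation = 1L)
  bundle <- list(table2 = table2, coefficients = coefficients,
                 updated_coefficients = updated_coefficients,
                 transitions = transitions, predictions = predictions,
                 validation_cohort = val_cohort, manifest = manifest)
  class(bundle) <- "study_bundle"
  if (!is.null(config$output_dir)) save_report(bundle, config$output_dir)
  invisible(bundle)
}

#' Load a cohort CSV (pipeline alias)
#'
#' @param path Cohort CSV path (see [read_cohort()] for the contract).
#' @return A [long_cohort()].
#' @export
load_cohort <- function(path) read_cohort(path)

#' Write a study bundle to disk
#'
#' Writes the report table (one CSV row per model, report-table order),
#' frozen and updated coefficient JSONs, Bland-Altman and scatter plot data
#' (two-column CSVs per model), the class-transition table, and a JSON run
#' manifest with every seed. All outputs are plain text and byte-stable
#' under a fixed configuration.
#'
#' @param bundle A bundle from [run_study()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$table2, file.path(path, "table2_report.csv"),
                   na = "")
  for (mode in names(bundle$coefficients)) {
    write_coefficients(bundle$coefficients[[mode]],
                       file.path(path, paste0("coefficients_", mode, ".json")))
  }
  for (label in names(bundle$updated_coefficients)) {
    uc <- bundle$updated_coefficients[[label]]
    if (inherits(uc, "egfr_model_coefficients")) {
      write_coefficients(uc, file.path(path,
                                       paste0("coefficients_", label,
                                              ".json")))
    } else {
      jsonlite::write_json(uc, file.path(path, paste0("coefficients_", label,
                                                      ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  for (label in names(bundle$predictions)) {
    pr <- bundle$predictions[[label]]
    readr::write_csv(
      tibble(mean_egfr = (pr$egfr_obs + pr$egfr_pred) / 2,
             diff_obs_minus_pred = pr$egfr_obs - pr$egfr_pred),
      file.path(path, paste0("bland_altman_", label, ".csv")))
    readr::write_csv(tibble(observed = pr$egfr_obs,
                            predicted = pr$egfr_pred),
                     file.path(path, paste0("scatter_", label, ".csv")))
  }
  tr <- bundle$transitions
  readr::write_csv(
    tibble(baseline_class = rep(rownames(tr$counts), times = 5),
           final_class = rep(colnames(tr$counts), each = 5),
           count = as.vector(tr$counts)),
    file.path(path, "transitions.csv"))
  manifest <- c(bundle$manifest,
                list(transitions = list(n_assessed = tr$n_assessed,
                                        pct_progressed = tr$pct_progressed,
                                        pct_regressed = tr$pct_regressed)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
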