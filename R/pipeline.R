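# Full-run orchestration: plates -> viability -> AUC -> responder classes ->
# regimen predictions -> cohort evaluation. Every stage writes its TSV so any
# downstream stage can be resumed from disk, and the JSON report is the
# single source for all reported statistics.

#' Pipeline run configuration
#'
#' @param plates path to the plate CSV.
#' @param cohort optional path to the cohort TSV.
#' @param panel optional panel JSON path (default: the standard 10-point
#'   panel for the drugs found on the plates).
#' @param regimens optional regimen JSON path (default map).
#' @param out_dir output directory (created if needed).
#' @param n_min minimal per-drug library size for classification.
#' @param override_n_min classify even below `n_min`.
#' @param k number of responder classes.
#' @param seed seed recorded in the report.
#' @return `run_config` list.
#' @export
run_config <- function(plates, cohort = NULL, panel = NULL, regimens = NULL,
                       out_dir = "pharmacotype_out", n_min = 25L,
                       override_n_min = FALSE, k = 3L, seed = 1L) {
  for (p in c(plates, cohort, panel, regimens)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("input path does not exist: %s", p))
  }
  list(plates = plates, cohort = cohort, panel = panel, regimens = regimens,
       out_dir = out_dir, n_min = as.integer(n_min),
       override_n_min = isTRUE(override_n_min), k = as.integer(k),
       seed = as.integer(seed))
}

#' Run the full pharmacotyping pipeline
#'
#' Executes all stages in order, writing per-stage TSVs, per-PDO
#' classification cards (per-drug AUC + responder category) and a JSON
#' report with every statistic, count and exclusion.
#'
#' @param config a [run_config()].
#' @return the report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- character(0)
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    log_lines <<- c(log_lines, sprintf("%s: %.2fs", name,
                                       as.numeric(Sys.time() - st, units = "secs")))
    res
  }

  wells <- stage("read_plates", read_plate(config$plates))
  drugs <- setdiff(unique(wells$drug_id), CONTROL_ID)
  panel <- stage("panel", {
    if (is.null(config$panel)) default_panel(drugs) else read_panel(config$panel)
  })
  regimens <- stage("regimens", {
    if (is.null(config$regimens)) default_regimens()
    else read_regimens(config$regimens, screened = drugs)
  })

  profiles <- stage("viability", compute_viability_all(wells, panel))
  library_ <- stage("auc", build_library(lapply(profiles, compute_auc)))
  write_auc_tsv(library_, file.path(config$out_dir, "auc.tsv"))

  classified <- stage("classify", {
    out <- lapply(colnames(library_), function(d) {
      classify_drug(library_, d, n_min = config$n_min,
                    override = config$override_n_min, k = config$k)
    })
    stats::setNames(out, colnames(library_))
  })
  write_classification_tsv(classified,
                           file.path(config$out_dir, "breaks.tsv"),
                           file.path(config$out_dir, "calls.tsv"))
  calls <- do.call(rbind, lapply(classified, `[[`, "calls"))

  predictions <- stage("predict", score_all_regimens(calls, regimens))
  utils::write.table(predictions, file.path(config$out_dir, "predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  stage("cards", write_pdo_cards(library_, calls,
                                 file.path(config$out_dir, "pdo_cards.txt")))

  evaluation <- NULL
  if (!is.null(config$cohort)) {
    evaluation <- stage("evaluate", {
      cohort <- read_cohort(config$cohort)
      evaluate_cohort(cohort, predictions)
    })
  }

  report <- list(
    seed = config$seed,
    n_pdos = nrow(library_),
    drugs = colnames(library_),
    breaks = lapply(classified, function(cl) {
      list(drug_id = cl$model$id, breaks = cl$model$breaks, gvf = cl$model$gvf,
           n = cl$model$n, cutoffs = cutoff_report(cl$model))
    }),
    n_predictions = nrow(predictions),
    evaluation = evaluation,
    log = log_lines,
    runtime_s = as.numeric(Sys.time() - t0, units = "secs")
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(report)
}

#' Evaluate a cohort against regimen predictions
#'
#' Joins each patient's received regimen to the PDO's predicted call and
#' computes pharmacotyping efficacy strata, prediction accuracy by treatment
#' status, and Kaplan-Meier PFS split by predicted call with a log-rank test.
#'
#' @param cohort patient records (needs `patient_id`, `pdo_id`,
#'   `histology_confirmed_pc`, `treatment_status`, `biopsy_site`,
#'   `pharmacotyped`, `regimen_received`, `best_response`, `pfs_days`,
#'   `pfs_event`).
#' @param predictions regimen predictions as from [score_all_regimens()].
#' @return nested list of statistics with counts and exclusions.
#' @export
evaluate_cohort <- function(cohort, predictions) {
  eff <- list(
    overall = pharmacotyping_efficacy(cohort),
    naive_liver = pharmacotyping_efficacy(
      cohort, cohort$treatment_status == "treatment-naive" &
        cohort$biopsy_site == "liver_metastasis"),
    naive_primary = pharmacotyping_efficacy(
      cohort, cohort$treatment_status == "treatment-naive" &
        cohort$biopsy_site == "primary"),
    pretreated = pharmacotyping_efficacy(cohort,
                                         cohort$treatment_status == "pretreated")
  )

  joined <- merge(cohort, predictions,
                  by.x = c("pdo_id", "regimen_received"),
                  by.y = c("pdo_id", "regimen"))
  acc <- NULL
  if (nrow(joined) > 0) {
    pred_df <- data.frame(patient_id = joined$patient_id, call = joined$call,
                          outcome = tumor_control(joined$best_response),
                          status = joined$treatment_status,
                          stringsAsFactors = FALSE)
    acc <- list(overall = prediction_accuracy(cohort, pred_df))
    for (st in unique(pred_df$status)) {
      flt <- pred_df$status == st
      if (any(pred_df$outcome[flt] != "not_available")) {
        acc[[st]] <- prediction_accuracy(cohort, pred_df, flt)
      }
    }
  }

  km <- NULL
  if (nrow(joined) > 0 && any(!is.na(joined$pfs_days))) {
    jj <- joined[!is.na(joined$pfs_days), , drop = FALSE]
    sens <- jj[jj$call == "sensitive", , drop = FALSE]
    res <- jj[jj$call == "resistant", , drop = FALSE]
    if (nrow(sens) > 0 && nrow(res) > 0) {
      km_s <- km_curve(sens$pfs_days, sens$pfs_event)
      km_r <- km_curve(res$pfs_days, res$pfs_event)
      lr <- logrank_test(sens$pfs_days, sens$pfs_event, res$pfs_days, res$pfs_event)
      km <- list(median_sensitive = km_s$median, median_resistant = km_r$median,
                 n_sensitive = km_s$n, n_resistant = km_r$n,
                 logrank_p = lr$p, logrank_chisq = lr$chisq)
    }
  }

  conc <- tryCatch(subtype_concordance(cohort), error = function(e) NULL)
  list(efficacy = eff, accuracy = acc, pfs = km, subtype = conc)
}

#' Write per-PDO classification cards
#'
#' One text block per PDO listing each drug's AUC and responder category —
#' the pipeline's human-readable per-patient profile.
#'
#' @param library an `auc_library`.
#' @param calls responder calls data.frame.
#' @param path output text path.
#' @return the path, invisibly.
#' @export
write_pdo_cards <- function(library, calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pdo in rownames(library)) {
    writeLines(sprintf("== %s ==", pdo), con)
    pc <- calls[calls$pdo_id == pdo, , drop = FALSE]
    for (i in seq_len(nrow(pc))) {
      auc <- unclass(library)[pdo, pc$drug_id[i]]
      writeLines(sprintf("  %-12s AUC %7.1f  %s responder",
                         pc$drug_id[i], auc, pc$category[i]), con)
    }
  }
  invisible(path)
}
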