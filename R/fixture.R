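# Deterministic trial-cohort fixture.
#
# A 54-sample synthetic reconstruction of the prospective pancreatic cancer
# organoid trial's printed aggregate counts: 44 histology-confirmed PC
# samples (10 non-PC exclusions), 30 treatment-naive patients (16 primary /
# 14 liver-metastasis biopsies; 8/16 and 11/14 pharmacotyped; among primary
# samples 11 percutaneous with 3 successes, 3 EUS-guided and 2 surgical all
# successful) and 14 pretreated patients (all liver, 9/14 pharmacotyped);
# evaluation rows giving 10/11 first-line, 4/5 second-line and 2/5
# pretreated prediction matches; and a subtype table with 16/21 concordant
# PDO-tissue pairs, 18/21 classical tissues and 19/25 classical PDOs.
#
# Only these aggregates are encoded; per-patient identities, Ki-67 values
# and all PFS fields are SYNTHETIC placeholders (the trial's per-patient
# survival was published in graphical form only), flagged by the
# `pfs_synthetic` column. No test treats median PFS of this fixture as a
# reproducible quantity.

#' Deterministic synthetic trial cohort fixture
#'
#' @return data.frame of 54 patient records with columns `patient_id`,
#'   `pdo_id`, `histology_confirmed_pc`, `treatment_status`, `prior_lines`,
#'   `tumor_stage`, `biopsy_site`, `sampling_method`, `pharmacotyped`,
#'   `regimen_received`, `therapy_line`, `best_response`, `pfs_days`,
#'   `pfs_event`, `pfs_synthetic`, `pdo_subtype`, `tissue_subtype`,
#'   `ki67_percent`.
#' @seealso [fixture_predictions()] for the matching per-line prediction
#'   rows.
#' @export
fixture_cohort <- function() {
  n <- 54L
  df <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    pdo_id = NA_character_,
    histology_confirmed_pc = c(rep(TRUE, 44), rep(FALSE, 10)),
    treatment_status = c(rep("treatment-naive", 30), rep("pretreated", 14),
                         rep("treatment-naive", 10)),
    prior_lines = 0L,
    tumor_stage = NA_character_,
    biopsy_site = NA_character_,
    sampling_method = NA_character_,
    pharmacotyped = FALSE,
    regimen_received = NA_character_,
    therapy_line = NA_integer_,
    best_response = "not_available",
    pfs_days = NA_real_,
    pfs_event = NA_integer_,
    pfs_synthetic = TRUE,
    pdo_subtype = "unknown",
    tissue_subtype = "unknown",
    ki67_percent = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$patient_id

  # --- treatment-naive, primary tumor (16) -------------------------------
  # percutaneous US biopsies (11): 3 pharmacotyped
  df[1:11, "biopsy_site"] <- "primary"
  df[1:11, "sampling_method"] <- "us_biopsy"
  df[1:3, "pharmacotyped"] <- TRUE
  # EUS-guided FNB (3): all pharmacotyped
  df[12:14, "biopsy_site"] <- "primary"
  df[12:14, "sampling_method"] <- "eus_fnb"
  df[12:14, "pharmacotyped"] <- TRUE
  # surgical resections (2): all pharmacotyped
  df[15:16, "biopsy_site"] <- "primary"
  df[15:16, "sampling_method"] <- "surgical"
  df[15:16, "pharmacotyped"] <- TRUE

  # --- treatment-naive, liver metastases (14): 11 pharmacotyped ----------
  df[17:30, "biopsy_site"] <- "liver_metastasis"
  df[17:30, "sampling_method"] <- "us_biopsy"
  df[17:27, "pharmacotyped"] <- TRUE

  # tumor stage: 18 metastasized among the naive (all 14 liver + 4 primary)
  df[1:30, "tumor_stage"] <- "locally_advanced"
  df[c(4:7, 17:30), "tumor_stage"] <- "metastasized"
  df[13:16, "tumor_stage"] <- "resectable"

  # --- pretreated (14): all liver US biopsies, 9 pharmacotyped -----------
  df[31:44, "biopsy_site"] <- "liver_metastasis"
  df[31:44, "sampling_method"] <- "us_biopsy"
  df[31:44, "tumor_stage"] <- "metastasized"
  df[31:39, "pharmacotyped"] <- TRUE
  df[31:44, "prior_lines"] <- c(1L, 1L, 1L, 2L, 4L, 2L, 2L, 1L, 2L,
                                2L, 2L, 3L, 3L, 3L)

  # --- non-PC exclusions (10) -------------------------------------------
  df[45:54, "biopsy_site"] <- "primary"
  df[45:54, "sampling_method"] <- "us_biopsy"
  df[45:54, "tumor_stage"] <- NA_character_

  df$pdo_id[df$pharmacotyped] <- sprintf("PDO%02d", seq_len(sum(df$pharmacotyped)))

  # --- evaluation block: 16 evaluated patients ---------------------------
  pred <- fixture_predictions()
  first <- pred[pred$line == "first", , drop = FALSE]
  for (i in seq_len(nrow(first))) {
    pid <- first$patient_id[i]
    df[pid, "regimen_received"] <- first$regimen[i]
    df[pid, "therapy_line"] <- 1L
    df[pid, "best_response"] <- if (first$outcome[i] == "response") "PR" else "PD"
  }
  pre <- pred[pred$line == "pretreated", , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    pid <- pre$patient_id[i]
    df[pid, "regimen_received"] <- pre$regimen[i]
    df[pid, "therapy_line"] <- df[pid, "prior_lines"] + 1L
    df[pid, "best_response"] <- if (pre$outcome[i] == "response") "SD" else "PD"
  }

  # synthetic PFS for evaluated naive patients: longer under a sensitive-
  # predicted regimen, shorter under a resistant-predicted one (placeholder
  # values; never asserted)
  sens_first <- first$patient_id[first$call == "sensitive"]
  res_first <- setdiff(first$patient_id, sens_first)
  df[sens_first, "pfs_days"] <- seq(110, 110 + 20 * (length(sens_first) - 1), by = 20)
  df[res_first, "pfs_days"] <- seq(35, 35 + 15 * (length(res_first) - 1), by = 15)
  df[first$patient_id, "pfs_event"] <- rep(c(1L, 1L, 1L, 0L), length.out = nrow(first))

  # --- subtype table -----------------------------------------------------
  # 21 PDO-tissue pairs: 15 classical/classical, 3 classical tissue with
  # basal-like PDO (drift), 2 basal-like tissue with classical PDO, 1
  # basal/basal; plus 4 PDO-only calls (2 classical, 2 basal-like).
  pharma_ids <- df$patient_id[df$pharmacotyped]
  pair_ids <- pharma_ids[1:21]
  df[pair_ids[1:15], c("tissue_subtype", "pdo_subtype")] <-
    list("classical", "classical")
  df[pair_ids[16:18], c("tissue_subtype", "pdo_subtype")] <-
    list("classical", "basal_like")
  df[pair_ids[19:20], c("tissue_subtype", "pdo_subtype")] <-
    list("basal_like", "classical")
  df[pair_ids[21], c("tissue_subtype", "pdo_subtype")] <-
    list("basal_like", "basal_like")
  solo_ids <- pharma_ids[22:25]
  df[solo_ids[1:2], "pdo_subtype"] <- "classical"
  df[solo_ids[3:4], "pdo_subtype"] <- "basal_like"

  # synthetic Ki-67 indices for PDO-evaluable patients (placeholder values)
  df[pharma_ids[1:25], "ki67_percent"] <- rep(c(20, 35, 60, 75, 50), 5)

  rownames(df) <- NULL
  df
}

#' Per-line prediction rows matching the fixture cohort
#'
#' One row per evaluated patient x therapy line: 11 first-line treatment-
#' naive evaluations (10 matching), 5 second-line evaluations in the same
#' patients (4 matching) and 5 evaluations in pretreated patients
#' (2 matching).
#'
#' @return data.frame with columns `patient_id`, `line` (`first` / `second`
#'   / `pretreated`), `regimen`, `call` (`sensitive`/`resistant`), `outcome`
#'   (`response`/`no_response`).
#' @export
fixture_predictions <- function() {
  first <- data.frame(
    patient_id = sprintf("P%02d", 17:27), # naive liver-metastasis PDOs
    line = "first",
    regimen = c(rep("FOLFIRINOX", 5), rep("gemcitabine/nab-paclitaxel", 6)),
    call = c(rep("sensitive", 7), rep("resistant", 3), "sensitive"),
    outcome = c(rep("response", 7), rep("no_response", 4)),
    stringsAsFactors = FALSE
  )
  second <- data.frame(
    patient_id = sprintf("P%02d", 17:21),
    line = "second",
    regimen = c(rep("gemcitabine/nab-paclitaxel", 4), "5-FU/nab-paclitaxel"),
    call = c("sensitive", "sensitive", "resistant", "resistant", "sensitive"),
    outcome = c("response", "response", "no_response", "no_response", "no_response"),
    stringsAsFactors = FALSE
  )
  pretreated <- data.frame(
    patient_id = sprintf("P%02d", 31:35),
    line = "pretreated",
    regimen = c(rep("gemcitabine/nab-paclitaxel", 3), rep("nal-iri/5-FU", 2)),
    call = c("sensitive", "resistant", "resistant", "sensitive", "sensitive"),
    outcome = c("response", "response", "no_response", "no_response", "no_response"),
    stringsAsFactors = FALSE
  )
  rbind(first, second, pretreated)
}
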