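# Plate-reader I/O and screen configuration.
#
# All concentrations are stored internally in mol/L; nM/µM only appear in
# rendered reports. The two-step cytotoxicity assay reports a pre-lysis
# dead-cell signal (s1) and a post-lysis total signal (s2) per well; viable
# signal is s2 - s1.

CONTROL_ID <- "CONTROL"

#' Default ten-point concentration panel
#'
#' Ten log-spaced molar concentrations covering three orders of magnitude,
#' 13 nM to 50 uM, applied to every drug in the standard-of-care screen.
#'
#' @param drugs character vector of drug identifiers.
#' @return named list mapping drug_id to its 10 ascending molar concentrations.
#' @export
default_panel <- function(drugs = default_drugs()) {
  conc <- 10^seq(log10(1.3e-8), log10(5.0e-5), length.out = 10)
  stats::setNames(lapply(drugs, function(d) conc), drugs)
}

#' Standard-of-care screen drugs
#'
#' The five most commonly used standard-of-care chemotherapy compounds for
#' pancreatic cancer, screened as single agents.
#'
#' @return character vector of drug identifiers.
#' @export
default_drugs <- function() {
  c("gemcitabine", "paclitaxel", "irinotecan", "5-FU", "oxaliplatin")
}

#' Default regimen-to-drug map
#'
#' Combination regimens are mapped to their screened single-agent components.
#' Leucovorin (folinic acid, a modulator) and the nab-paclitaxel albumin
#' carrier are never components because they are not screened.
#'
#' @return named list mapping regimen name to component drug ids.
#' @export
default_regimens <- function() {
  list(
    "FOLFIRINOX"                 = c("5-FU", "irinotecan", "oxaliplatin"),
    "gemcitabine/nab-paclitaxel" = c("gemcitabine", "paclitaxel"),
    "gemcitabine"                = c("gemcitabine"),
    "nal-iri/5-FU"               = c("irinotecan", "5-FU"),
    "5-FU/nab-paclitaxel"        = c("5-FU", "paclitaxel")
  )
}

#' Validate a concentration panel
#'
#' @param panel named list drug_id -> ascending molar concentrations.
#' @param n_required required number of concentrations per drug (default 10).
#' @return the panel, invisibly, if valid; otherwise an error.
#' @export
validate_panel <- function(panel, n_required = 10L) {
  if (!is.list(panel) || is.null(names(panel)) || any(names(panel) == "")) {
    abort("panel must be a named list of concentration vectors")
  }
  for (d in names(panel)) {
    conc <- panel[[d]]
    if (length(conc) != n_required) {
      abort(sprintf("panel drug '%s': expected %d concentrations, got %d",
                    d, n_required, length(conc)))
    }
    if (any(!is.finite(conc)) || any(conc <= 0)) {
      abort(sprintf("panel drug '%s': concentrations must be positive finite mol/L", d))
    }
    if (any(diff(conc) <= 0)) {
      abort(sprintf("panel drug '%s': concentrations must be strictly increasing", d))
    }
  }
  invisible(panel)
}

#' Read plate-reader well measurements
#'
#' Long-format CSV with columns `pdo_id, drug_id, concentration_molar,
#' replicate, s1, s2`. Control wells carry `drug_id = CONTROL` and an empty
#' concentration. Every PDO plate must contain control wells.
#'
#' @param path CSV file path.
#' @param panel optional panel (named list) to validate concentrations against.
#' @return data.frame of well measurements (one row per well).
#' @export
read_plate <- function(path, panel = NULL) {
  if (!file.exists(path)) abort(sprintf("plate file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("pdo_id", "drug_id", "concentration_molar", "replicate", "s1", "s2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("plate file %s: missing column(s) %s",
                  path, paste(missing, collapse = ", ")))
  }
  df$concentration_molar <- suppressWarnings(as.numeric(df$concentration_molar))
  validate_wells(df, panel = panel, source = path)
  df
}

#' Validate a collection of well measurements
#'
#' @param wells data.frame as returned by [read_plate()].
#' @param panel optional panel to validate concentrations against.
#' @param source label used in error messages.
#' @return the wells, invisibly.
#' @export
validate_wells <- function(wells, panel = NULL, source = "wells") {
  is_ctrl <- wells$drug_id == CONTROL_ID
  bad_lum <- which(wells$s1 < 0 | wells$s2 < 0 | !is.finite(wells$s1) | !is.finite(wells$s2))
  if (length(bad_lum) > 0) {
    abort(sprintf("%s: negative or non-finite luminescence at row %d", source, bad_lum[1]))
  }
  bad_rep <- which(!(wells$replicate %in% seq_len(max(1, max(wells$replicate)))))
  if (any(wells$replicate < 1 | wells$replicate != round(wells$replicate))) {
    abort(sprintf("%s: replicate indices must be positive integers", source))
  }
  bad_conc <- which(!is_ctrl & (!is.finite(wells$concentration_molar) | wells$concentration_molar <= 0))
  if (length(bad_conc) > 0) {
    abort(sprintf("%s: missing or non-positive concentration at row %d (drug wells need mol/L)",
                  source, bad_conc[1]))
  }
  for (pdo in unique(wells$pdo_id)) {
    if (!any(is_ctrl & wells$pdo_id == pdo)) {
      abort(sprintf("%s: no control wells for PDO '%s'", source, pdo))
    }
  }
  if (!is.null(panel)) {
    drug_rows <- wells[!is_ctrl, , drop = FALSE]
    for (d in unique(drug_rows$drug_id)) {
      if (!d %in% names(panel)) {
        abort(sprintf("%s: drug '%s' not in declared panel", source, d))
      }
      conc <- drug_rows$concentration_molar[drug_rows$drug_id == d]
      known <- vapply(conc, function(cc) {
        any(abs(cc - panel[[d]]) <= 1e-9 * pmax(cc, panel[[d]]))
      }, logical(1))
      if (!all(known)) {
        bad <- which(drug_rows$drug_id == d)[which(!known)[1]]
        abort(sprintf("%s: concentration %g not in declared panel for drug '%s' (row %d)",
                      source, conc[which(!known)[1]], d, bad))
      }
    }
  }
  invisible(wells)
}

#' Write well measurements to CSV
#'
#' Inverse of [read_plate()]; round-trips all fields.
#'
#' @param wells data.frame of well measurements.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_plate <- function(wells, path) {
  out <- wells[, c("pdo_id", "drug_id", "concentration_molar", "replicate", "s1", "s2")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a drug panel JSON
#'
#' JSON object mapping `drug_id` to its array of molar concentrations.
#'
#' @param path JSON file path.
#' @return validated panel (named list).
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("panel file not found: %s", path))
  panel <- jsonlite::read_json(path, simplifyVector = TRUE)
  panel <- lapply(panel, as.numeric)
  validate_panel(panel)
  panel
}

#' Write a drug panel JSON
#' @param panel named list drug_id -> molar concentrations.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(panel, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a regimen-to-drug map
#'
#' JSON object mapping regimen name to an array of component drug ids; every
#' component must be part of the screened panel.
#'
#' @param path JSON file path.
#' @param screened character vector of screened drug ids components must
#'   belong to (default the standard screen).
#' @return named list regimen -> component drugs.
#' @export
read_regimens <- function(path, screened = default_drugs()) {
  if (!file.exists(path)) abort(sprintf("regimen file not found: %s", path))
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- lapply(reg, as.character)
  validate_regimens(reg, screened)
  reg
}

#' Validate a regimen map against the screened panel
#' @param regimens named list regimen -> component drug ids.
#' @param screened screened drug ids.
#' @return the map, invisibly.
#' @export
validate_regimens <- function(regimens, screened = default_drugs()) {
  if (!is.list(regimens) || is.null(names(regimens))) {
    abort("regimens must be a named list of drug id vectors")
  }
  for (r in names(regimens)) {
    comp <- regimens[[r]]
    if (length(comp) == 0) abort(sprintf("regimen '%s' has an empty drug list", r))
    unknown <- setdiff(comp, screened)
    if (length(unknown) > 0) {
      abort(sprintf("regimen '%s' includes unscreened drug(s): %s",
                    r, paste(unknown, collapse = ", ")))
    }
  }
  invisible(regimens)
}

#' Write a regimen map JSON
#' @param regimens named list regimen -> component drugs.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_regimens <- function(regimens, path) {
  jsonlite::write_json(regimens, path, auto_unbox = FALSE)
  invisible(path)
}
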