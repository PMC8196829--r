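# Viability normalization and dose-response AUC.
#
# Percent viability per concentration is the net viable luminescence of the
# drug wells relative to the untreated control wells of the same PDO plate:
#   viability% = 100 * mean_reps(s2 - s1)_drug / mean_reps(s2 - s1)_ctrl
# The curve is summarized as the trapezoidal area under viability vs
# log10(concentration), baseline 0. Viability is not capped at 100%
# (stimulated wells are preserved); negative net drug signal clips to 0.
# No sigmoid/IC50 fitting is performed: the raw trapezoidal AUC is the score.

#' Compute a dose-response profile for one PDO x drug
#'
#' @param wells data.frame of well measurements containing drug wells for
#'   `pdo_id` x `drug_id` and control wells (`drug_id = "CONTROL"`) for the
#'   same PDO.
#' @param panel concentration panel (named list); the drug's declared
#'   concentrations must all be measured.
#' @param pdo_id,drug_id identify the curve; defaults are inferred when the
#'   input contains exactly one PDO and one non-control drug.
#' @return object of class `dose_response_profile` with elements `pdo_id`,
#'   `drug_id`, `concentration` (mol/L ascending), `viability` (percent),
#'   and `replicate_viability` (list of per-replicate percent values).
#' @export
compute_viability <- function(wells, panel, pdo_id = NULL, drug_id = NULL) {
  if (is.null(pdo_id)) {
    pdos <- unique(wells$pdo_id)
    if (length(pdos) != 1) abort("pdo_id must be given when wells span several PDOs")
    pdo_id <- pdos
  }
  if (is.null(drug_id)) {
    drugs <- setdiff(unique(wells$drug_id), CONTROL_ID)
    if (length(drugs) != 1) abort("drug_id must be given when wells span several drugs")
    drug_id <- drugs
  }
  if (!drug_id %in% names(panel)) abort(sprintf("drug '%s' not in panel", drug_id))

  ctrl <- wells[wells$pdo_id == pdo_id & wells$drug_id == CONTROL_ID, , drop = FALSE]
  if (nrow(ctrl) == 0) abort(sprintf("no control wells for PDO '%s'", pdo_id))
  ctrl_net <- mean(ctrl$s2 - ctrl$s1)
  if (ctrl_net <= 0) {
    abort(sprintf("degenerate control for PDO '%s': mean (s2 - s1) = %g <= 0",
                  pdo_id, ctrl_net))
  }

  drug <- wells[wells$pdo_id == pdo_id & wells$drug_id == drug_id, , drop = FALSE]
  conc <- sort(panel[[drug_id]])
  viability <- numeric(length(conc))
  rep_viab <- vector("list", length(conc))
  for (i in seq_along(conc)) {
    rows <- drug[abs(drug$concentration_molar - conc[i]) <=
                   1e-9 * pmax(drug$concentration_molar, conc[i]), , drop = FALSE]
    if (nrow(rows) == 0) {
      abort(sprintf("PDO '%s' drug '%s': no wells at %g mol/L", pdo_id, drug_id, conc[i]))
    }
    net <- rows$s2 - rows$s1
    if (any(net < 0)) {
      warning(sprintf("PDO '%s' drug '%s' at %g mol/L: negative net signal clipped to 0",
                      pdo_id, drug_id, conc[i]), call. = FALSE)
      net <- pmax(net, 0)
    }
    rv <- 100 * net / ctrl_net
    rep_viab[[i]] <- rv
    viability[i] <- mean(rv)
  }
  structure(
    list(pdo_id = pdo_id, drug_id = drug_id, concentration = conc,
         viability = viability, replicate_viability = rep_viab),
    class = "dose_response_profile"
  )
}

#' Compute all dose-response profiles on a plate collection
#'
#' @param wells data.frame of well measurements (several PDOs/drugs).
#' @param panel concentration panel.
#' @return list of `dose_response_profile` objects, one per PDO x drug pair.
#' @export
compute_viability_all <- function(wells, panel) {
  profiles <- list()
  for (w in split(wells, wells$pdo_id)) {
    for (d in setdiff(unique(w$drug_id), CONTROL_ID)) {
      profiles[[length(profiles) + 1]] <-
        compute_viability(w, panel, pdo_id = w$pdo_id[1], drug_id = d)
    }
  }
  profiles
}

#' Trapezoidal AUC of a dose-response curve on the log10-dose axis
#'
#' `auc = sum over adjacent pairs of 0.5 * (v_i + v_{i+1}) *
#' (log10 c_{i+1} - log10 c_i)`, viability in percent, baseline 0. A constant
#' 100% curve on the default 13 nM - 50 uM panel gives 100 * log10(5.0e-5 /
#' 1.3e-8) = 358.50. AUC is invariant to a common rescaling of all
#' concentrations (units cancel in the log ratio).
#'
#' @param profile a `dose_response_profile`, or a list with elements
#'   `concentration` and `viability`.
#' @return list with `pdo_id`, `drug_id`, `auc`.
#' @export
compute_auc <- function(profile) {
  conc <- profile$concentration
  v <- profile$viability
  if (length(conc) < 2) abort("AUC needs at least 2 concentrations")
  if (any(diff(conc) <= 0)) abort("concentrations must be strictly increasing")
  if (any(v < 0)) abort("viability must be >= 0 (clip before integrating)")
  x <- log10(conc)
  auc <- sum(0.5 * (v[-length(v)] + v[-1]) * diff(x))
  list(pdo_id = profile$pdo_id %||% NA_character_,
       drug_id = profile$drug_id %||% NA_character_,
       auc = auc)
}

#' Build a PDO x drug AUC library
#'
#' @param records data.frame with columns `pdo_id`, `drug_id`, `auc`, or a
#'   list of records as returned by [compute_auc()].
#' @return object of class `auc_library`: a numeric matrix (rows = PDOs,
#'   cols = drugs, `NA` = untested pair) with accessors [drug_vector()].
#' @export
build_library <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      data.frame(pdo_id = r$pdo_id, drug_id = r$drug_id, auc = r$auc,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(records) || nrow(records) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(structure(m, class = c("auc_library", "matrix")))
  }
  key <- paste(records$pdo_id, records$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE][1, ]
    abort(sprintf("duplicate (pdo, drug) pair: (%s, %s)", dup$pdo_id, dup$drug_id))
  }
  pdos <- unique(records$pdo_id)
  drugs <- unique(records$drug_id)
  m <- matrix(NA_real_, nrow = length(pdos), ncol = length(drugs),
              dimnames = list(pdos, drugs))
  m[cbind(match(records$pdo_id, pdos), match(records$drug_id, drugs))] <- records$auc
  structure(m, class = c("auc_library", "matrix"))
}

#' Extract one drug's AUC vector from a library
#'
#' @param library an `auc_library`.
#' @param drug_id drug column to extract.
#' @return named numeric vector (PDO ids), missing pairs dropped.
#' @export
drug_vector <- function(library, drug_id) {
  if (!drug_id %in% colnames(library)) {
    abort(sprintf("drug '%s' not in library", drug_id))
  }
  v <- library[, drug_id]
  v[!is.na(v)]
}

#' Write an AUC library as long-format TSV
#' @param library an `auc_library`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_auc_tsv <- function(library, path) {
  long <- as.data.frame(as.table(unclass(library)), stringsAsFactors = FALSE)
  names(long) <- c("pdo_id", "drug_id", "auc")
  long <- long[!is.na(long$auc), , drop = FALSE]
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an AUC library from long-format TSV
#' @param path TSV with columns pdo_id, drug_id, auc.
#' @return an `auc_library`.
#' @export
read_auc_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("AUC file not found: %s", path))
  build_library(utils::read.delim(path, stringsAsFactors = FALSE))
}
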