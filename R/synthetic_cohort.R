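# Synthetic plates and cohorts with known ground truth.
#
# The plate generator draws, per PDO x drug, a responder archetype (high /
# intermediate / low) and an IC50 around the archetype's log-molar mean, then
# emits two-signal wells whose viability follows a four-parameter logistic in
# log10 dose:
#   V(c) = floor + (100 - floor) / (1 + 10^(hill * (log10 c - log10 IC50)))
# Control wells carry exactly the configured control signal; drug wells get
# multiplicative Gaussian replicate noise on the net signal. The cohort
# generator assigns each patient a regimen, derives the true regimen
# sensitivity from the archetype scores, flips the clinical outcome with a
# configurable label-noise probability (higher for pretreated patients, where
# microenvironment-driven resistance is not captured ex vivo), and draws
# exponential progression-free survival with a sensitivity-dependent scale.
#
# Three decoupled pseudo-random streams (ground truth, plate noise, clinical
# outcomes/censoring) are derived from the one seed, so regenerating one
# artifact leaves the others byte-identical.

#' Generator configuration
#'
#' @param n_pdos number of PDOs / patients (default 28, a full library).
#' @param drugs screened drug ids.
#' @param panel concentration panel (named list, mol/L).
#' @param archetype_probs probabilities of the high / intermediate / low
#'   responder archetypes (sum to 1).
#' @param log10_ic50_means per-archetype mean log10 IC50 (mol/L); defaults to
#'   0.1x, 1x and 10x the panel's geometric mid-dose.
#' @param log10_ic50_sd within-archetype spread of log10 IC50 (default 0.25).
#' @param hill_slope Hill slope of the logistic (default 1).
#' @param floor_viability bottom plateau viability in percent (default 5).
#' @param replicate_sd multiplicative replicate noise on net signal, percent
#'   (default 5).
#' @param n_replicates wells per concentration (default 2).
#' @param control_signal net control luminescence (RLU, default 10000).
#' @param background pre-lysis background signal s1 (RLU, default 500).
#' @param label_noise probability a treatment-naive clinical outcome
#'   contradicts the true regimen sensitivity (default 0.1).
#' @param pretreated_label_noise same for pretreated patients (default 0.6).
#' @param pretreated_prob fraction of pretreated patients (default 0.3).
#' @param pfs_scale_sensitive,pfs_scale_resistant exponential PFS scales
#'   (mean days) for truly sensitive / resistant regimens (defaults 141, 46).
#' @param censor_prob probability a PFS observation is censored (default 0.2).
#' @param seed master seed.
#' @return validated `generator_config` list.
#' @export
generator_config <- function(n_pdos = 28L,
                             drugs = default_drugs(),
                             panel = default_panel(drugs),
                             archetype_probs = c(high = 1 / 3, intermediate = 1 / 3, low = 1 / 3),
                             log10_ic50_means = NULL,
                             log10_ic50_sd = 0.25,
                             hill_slope = 1,
                             floor_viability = 5,
                             replicate_sd = 5,
                             n_replicates = 2L,
                             control_signal = 10000,
                             background = 500,
                             label_noise = 0.1,
                             pretreated_label_noise = 0.6,
                             pretreated_prob = 0.3,
                             pfs_scale_sensitive = 141,
                             pfs_scale_resistant = 46,
                             censor_prob = 0.2,
                             seed = 1L) {
  if (is.null(log10_ic50_means)) {
    mid <- mean(log10(range(panel[[1]])))
    log10_ic50_means <- c(high = mid - 1, intermediate = mid, low = mid + 1)
  }
  cfg <- list(n_pdos = as.integer(n_pdos), drugs = drugs, panel = panel,
              archetype_probs = archetype_probs,
              log10_ic50_means = log10_ic50_means,
              log10_ic50_sd = log10_ic50_sd, hill_slope = hill_slope,
              floor_viability = floor_viability, replicate_sd = replicate_sd,
              n_replicates = as.integer(n_replicates),
              control_signal = control_signal, background = background,
              label_noise = label_noise,
              pretreated_label_noise = pretreated_label_noise,
              pretreated_prob = pretreated_prob,
              pfs_scale_sensitive = pfs_scale_sensitive,
              pfs_scale_resistant = pfs_scale_resistant,
              censor_prob = censor_prob, seed = as.integer(seed))
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#' @param cfg a `generator_config` list.
#' @return the config, invisibly.
#' @export
validate_generator_config <- function(cfg) {
  p <- cfg$archetype_probs
  if (length(p) != 3 || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
    abort("archetype_probs must be 3 probabilities summing to 1")
  }
  if (cfg$hill_slope <= 0) abort("hill_slope must be > 0")
  if (cfg$floor_viability < 0) abort("floor_viability must be >= 0")
  if (cfg$pfs_scale_sensitive <= cfg$pfs_scale_resistant) {
    abort("pfs_scale_sensitive must exceed pfs_scale_resistant")
  }
  if (cfg$label_noise < 0 || cfg$label_noise > 1 ||
      cfg$pretreated_label_noise < 0 || cfg$pretreated_label_noise > 1 ||
      cfg$censor_prob < 0 || cfg$censor_prob > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  validate_panel(cfg$panel)
  invisible(cfg)
}

#' Four-parameter logistic viability in log10 dose
#'
#' @param conc molar concentration(s).
#' @param log10_ic50 log10 IC50 (mol/L).
#' @param hill Hill slope (> 0).
#' @param floor bottom plateau, percent.
#' @return viability in percent; equals `(100 + floor) / 2` at the IC50.
#' @export
logistic_viability <- function(conc, log10_ic50, hill = 1, floor = 0) {
  floor + (100 - floor) / (1 + 10^(hill * (log10(conc) - log10_ic50)))
}

# archetype + IC50 ground truth; its own stream so plates and cohort agree
draw_truth <- function(cfg) {
  with_seed(cfg$seed * 7L + 101L, {
    arch_levels <- c("high", "intermediate", "low")
    rows <- expand.grid(pdo_id = sprintf("PDO%03d", seq_len(cfg$n_pdos)),
                        drug_id = cfg$drugs, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    rows <- rows[order(rows$pdo_id, rows$drug_id), , drop = FALSE]
    rows$archetype <- sample(arch_levels, nrow(rows), replace = TRUE,
                             prob = cfg$archetype_probs)
    rows$log10_ic50 <- cfg$log10_ic50_means[rows$archetype] +
      stats::rnorm(nrow(rows), 0, cfg$log10_ic50_sd)
    rows$true_score <- match(rows$archetype, arch_levels)
    rownames(rows) <- NULL
    rows
  })
}

#' Generate synthetic drug-screen plates
#'
#' @param cfg a `generator_config`.
#' @return list with `wells` (long-format well data.frame) and `truth`
#'   (per PDO x drug archetype, log10 IC50, true score).
#' @export
generate_plates <- function(cfg) {
  validate_generator_config(cfg)
  truth <- draw_truth(cfg)
  wells <- with_seed(cfg$seed * 7L + 202L, {
    out <- vector("list", nrow(truth) + cfg$n_pdos)
    k <- 0
    for (i in seq_len(nrow(truth))) {
      conc <- cfg$panel[[truth$drug_id[i]]]
      v <- logistic_viability(conc, truth$log10_ic50[i], cfg$hill_slope,
                              cfg$floor_viability)
      nrep <- cfg$n_replicates
      noise <- stats::rnorm(length(conc) * nrep, 0, cfg$replicate_sd / 100)
      net <- pmax(0, cfg$control_signal * rep(v, each = nrep) / 100 * (1 + noise))
      k <- k + 1
      out[[k]] <- data.frame(
        pdo_id = truth$pdo_id[i], drug_id = truth$drug_id[i],
        concentration_molar = rep(conc, each = nrep),
        replicate = rep(seq_len(nrep), times = length(conc)),
        s1 = cfg$background, s2 = cfg$background + net,
        stringsAsFactors = FALSE
      )
    }
    for (pdo in unique(truth$pdo_id)) {
      k <- k + 1
      out[[k]] <- data.frame(
        pdo_id = pdo, drug_id = CONTROL_ID, concentration_molar = NA_real_,
        replicate = seq_len(cfg$n_replicates), s1 = cfg$background,
        s2 = cfg$background + cfg$control_signal, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  list(wells = wells, truth = truth)
}

#' Generate a synthetic clinical cohort
#'
#' Patients map 1:1 to the generator's PDOs; the true regimen sensitivity is
#' the mean of the component drugs' true archetype scores (sensitive iff
#' <= 2), the recorded outcome flips with the applicable label noise, and
#' PFS is exponential with the sensitivity-dependent scale.
#'
#' @param cfg a `generator_config`.
#' @param regimens named list regimen -> component drugs.
#' @return list with `cohort` (patient records), `predictions` (per-patient
#'   true-sensitivity calls joined to recorded outcomes, ready for
#'   [prediction_accuracy()]) and `truth` (per-patient ground truth).
#' @export
generate_cohort <- function(cfg, regimens = default_regimens()) {
  validate_generator_config(cfg)
  drug_truth <- draw_truth(cfg)
  n <- cfg$n_pdos
  pdo_ids <- sprintf("PDO%03d", seq_len(n))
  naive_regs <- intersect(c("FOLFIRINOX", "gemcitabine/nab-paclitaxel"), names(regimens))
  pre_regs <- intersect(c("gemcitabine/nab-paclitaxel", "nal-iri/5-FU"), names(regimens))
  if (length(naive_regs) == 0 || length(pre_regs) == 0) {
    abort("regimens must include at least one first-line and one later-line option")
  }
  out <- with_seed(cfg$seed * 7L + 303L, {
    pretreated <- stats::runif(n) < cfg$pretreated_prob
    regimen <- ifelse(pretreated,
                      sample(pre_regs, n, replace = TRUE),
                      sample(naive_regs, n, replace = TRUE))
    true_sensitive <- vapply(seq_len(n), function(i) {
      comp <- regimens[[regimen[i]]]
      sc <- drug_truth$true_score[drug_truth$pdo_id == pdo_ids[i] &
                                    drug_truth$drug_id %in% comp]
      mean(sc) <= 2
    }, logical(1))
    noise_p <- ifelse(pretreated, cfg$pretreated_label_noise, cfg$label_noise)
    flip <- stats::runif(n) < noise_p
    outcome_resp <- xor(true_sensitive, flip)
    recist <- ifelse(outcome_resp,
                     sample(c("CR", "PR", "SD"), n, replace = TRUE,
                            prob = c(0.05, 0.35, 0.60)),
                     "PD")
    scale <- ifelse(true_sensitive, cfg$pfs_scale_sensitive, cfg$pfs_scale_resistant)
    pfs <- stats::rexp(n, rate = 1 / scale)
    list(pretreated = pretreated, regimen = regimen,
         true_sensitive = true_sensitive, flip = flip,
         outcome_resp = outcome_resp, recist = recist, pfs = pfs)
  })
  cens <- with_seed(cfg$seed * 7L + 404L, {
    censored <- stats::runif(n) < cfg$censor_prob
    frac <- stats::runif(n)
    list(censored = censored, frac = frac)
  })
  pfs_days <- ifelse(cens$censored, pmax(1, round(out$pfs * cens$frac)),
                     pmax(1, round(out$pfs)))
  prior <- ifelse(out$pretreated, 1L + (seq_len(n) %% 3L), 0L)
  cohort <- data.frame(
    patient_id = sprintf("PAT%03d", seq_len(n)),
    pdo_id = pdo_ids,
    histology_confirmed_pc = TRUE,
    treatment_status = ifelse(out$pretreated, "pretreated", "treatment-naive"),
    prior_lines = prior,
    biopsy_site = ifelse(out$pretreated, "liver_metastasis",
                         rep(c("primary", "liver_metastasis"), length.out = n)),
    sampling_method = "us_biopsy",
    pharmacotyped = TRUE,
    regimen_received = out$regimen,
    therapy_line = prior + 1L,
    best_response = out$recist,
    pfs_days = pfs_days,
    pfs_event = as.integer(!cens$censored),
    pdo_subtype = "unknown",
    tissue_subtype = "unknown",
    ki67_percent = NA_real_,
    stringsAsFactors = FALSE
  )
  predictions <- data.frame(
    patient_id = cohort$patient_id,
    line = ifelse(out$pretreated, "pretreated", "first"),
    regimen = out$regimen,
    call = ifelse(out$true_sensitive, "sensitive", "resistant"),
    outcome = tumor_control(cohort$best_response),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = cohort$patient_id, pdo_id = pdo_ids, regimen = out$regimen,
    true_sensitive = out$true_sensitive,
    outcome_before_noise = out$true_sensitive, label_flipped = out$flip,
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, predictions = predictions, truth = truth)
}
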