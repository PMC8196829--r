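# Cohort-level evaluation statistics.
#
# All tests are implemented directly (hypergeometric enumeration, exact
# rank-permutation null, product-limit estimator, log-rank chi-square) and
# are cross-checked in the test suite against the independent reference
# implementations in stats and survival. Percentages are reported rounded
# half-up to one decimal.

#' Map a RECIST best response to tumor control
#'
#' Complete response (CR), partial response (PR) and stable disease (SD)
#' count as tumor control (`"response"`); progressive disease (PD) as
#' `"no_response"`; unavailable restaging stays `"not_available"` and is
#' excluded from accuracy denominators.
#'
#' @param best_response character vector of `CR`, `PR`, `SD`, `PD`,
#'   `not_available`.
#' @return character vector of `response` / `no_response` / `not_available`.
#' @export
tumor_control <- function(best_response) {
  valid <- c("CR", "PR", "SD", "PD", "not_available")
  if (!all(best_response %in% valid)) {
    abort(sprintf("invalid RECIST category '%s'",
                  setdiff(best_response, valid)[1]))
  }
  out <- rep("not_available", length(best_response))
  out[best_response %in% c("CR", "PR", "SD")] <- "response"
  out[best_response == "PD"] <- "no_response"
  out
}

#' Pharmacotyping efficacy of a cohort stratum
#'
#' Proportion of histology-confirmed pancreatic cancer samples in a stratum
#' whose PDO culture reached drug testing.
#'
#' @param cohort data.frame of patient records (needs logical columns
#'   `histology_confirmed_pc`, `pharmacotyped`).
#' @param stratum_filter optional logical vector (length nrow(cohort)) or a
#'   function of the cohort returning one; applied before the confirmed-PC
#'   restriction.
#' @return list with `percent` (1 decimal, half-up), `numerator`,
#'   `denominator`.
#' @export
pharmacotyping_efficacy <- function(cohort, stratum_filter = NULL) {
  keep <- rep(TRUE, nrow(cohort))
  if (is.function(stratum_filter)) keep <- stratum_filter(cohort)
  else if (!is.null(stratum_filter)) keep <- stratum_filter
  sub <- cohort[keep & cohort$histology_confirmed_pc, , drop = FALSE]
  if (nrow(sub) == 0) abort("empty stratum after filtering to confirmed PC")
  num <- sum(sub$pharmacotyped)
  den <- nrow(sub)
  list(percent = round_half_up(100 * num / den, 1), numerator = num,
       denominator = den)
}

#' Prediction accuracy against clinical outcome
#'
#' A prediction matches when a sensitive call meets tumor control or a
#' resistant call meets progression. Patients without restaging
#' (`not_available` outcome) are excluded from the denominator and counted.
#'
#' @param cohort data.frame of patient records (column `patient_id`).
#' @param predictions data.frame with columns `patient_id`, `call`
#'   (`sensitive`/`resistant`), `outcome` (`response`/`no_response`/
#'   `not_available`), typically one row per evaluated patient x therapy
#'   line.
#' @param line_filter optional logical vector over `predictions` rows (or a
#'   function of `predictions`).
#' @return list with `percent`, `matches`, `evaluated`, `excluded`, and the
#'   2x2 `confusion` matrix (call x outcome).
#' @export
prediction_accuracy <- function(cohort, predictions, line_filter = NULL) {
  keep <- rep(TRUE, nrow(predictions))
  if (is.function(line_filter)) keep <- line_filter(predictions)
  else if (!is.null(line_filter)) keep <- line_filter
  pred <- predictions[keep, , drop = FALSE]
  if (!all(pred$patient_id %in% cohort$patient_id)) {
    abort("prediction for unknown patient id")
  }
  excluded <- sum(pred$outcome == "not_available")
  pred <- pred[pred$outcome != "not_available", , drop = FALSE]
  if (nrow(pred) == 0) abort("no evaluable patients (all outcomes unavailable)")
  match_ <- (pred$call == "sensitive" & pred$outcome == "response") |
    (pred$call == "resistant" & pred$outcome == "no_response")
  tab <- table(factor(pred$call, c("sensitive", "resistant")),
               factor(pred$outcome, c("response", "no_response")))
  confusion <- matrix(as.integer(tab), 2, 2,
                      dimnames = list(call = c("sensitive", "resistant"),
                                      outcome = c("response", "no_response")))
  list(percent = round_half_up(100 * sum(match_) / nrow(pred), 1),
       matches = sum(match_), evaluated = nrow(pred), excluded = excluded,
       confusion = confusion)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p-value by direct enumeration over the hypergeometric support with
#' fixed margins: the two-sided p is the sum of probabilities of all tables
#' whose probability does not exceed the observed table's (with a 1e-7
#' relative guard against floating-point under-counting).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return the exact two-sided p-value.
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) abort("counts must be non-negative integers")
  if (sum(tab) == 0) abort("all-zero table")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  # hypergeometric log-pmf from first principles
  logp <- function(a) {
    lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1)
  }
  lp <- logp(support)
  p_obs <- exp(logp(tab[1, 1]))
  min(1, sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact rank-permutation null (enumeration of all group assignments) when
#' the combined sample size is at most `exact_max`; otherwise the normal
#' approximation with tie correction. The two-sided p is the null
#' probability of a U at least as far from its mean as observed.
#'
#' @param x,y numeric samples.
#' @param exact_max maximum combined n for exact enumeration (default 20).
#' @return the two-sided p-value.
#' @export
mann_whitney_two_sided <- function(x, y, exact_max = 20L) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  combined <- c(x, y)
  r <- rank(combined)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (nx + ny <= exact_max) {
    idx <- utils::combn(nx + ny, nx)
    rank_sums <- colSums(matrix(r[idx], nrow = nx))
    u_all <- rank_sums - nx * (nx + 1) / 2
    return(mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
  }
  ties <- table(r)
  n <- nx + ny
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2) # continuity correction
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Kaplan-Meier product-limit curve
#'
#' @param time event/censoring times in days (>= 0).
#' @param event 1 = progression observed, 0 = censored. Censoring at a time
#'   t is handled after events at t (standard convention).
#' @return object of class `km_curve`: `time` (distinct event times),
#'   `surv` (S(t) after each event time), `n_risk`, `n_event`,
#'   `median` (first t with S(t) <= 0.5; `NA` if never reached).
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) abort("empty survival input")
  if (any(time < 0)) abort("negative survival time")
  if (!all(event %in% c(0, 1))) abort("event flags must be 0/1")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  etimes <- sort(unique(time[event == 1]))
  surv <- numeric(length(etimes))
  n_risk <- integer(length(etimes))
  n_event <- integer(length(etimes))
  s <- 1
  for (i in seq_along(etimes)) {
    t <- etimes[i]
    n_risk[i] <- sum(time >= t)
    n_event[i] <- sum(time == t & event == 1)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  med <- if (any(surv <= 0.5)) etimes[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = etimes, surv = surv, n_risk = n_risk,
                 n_event = n_event, median = med, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, median = %s days\n",
              x$n, length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square over the pooled event times, two-sided.
#'
#' @param time_a,event_a group A times and 0/1 event flags.
#' @param time_b,event_b group B times and 0/1 event flags.
#' @return list with `chisq`, `p`, `observed` and `expected` events in group
#'   A. A group without events triggers a warning, not an error.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) abort("both groups must be non-empty")
  if (sum(event_a) == 0 || sum(event_b) == 0) {
    warning("a group has zero events; log-rank p is still computed", call. = FALSE)
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1L, 2L), c(length(time_a), length(time_b)))
  etimes <- sort(unique(time[event == 1]))
  o_a <- 0; e_a <- 0; v <- 0
  for (t in etimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 1L)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == 1L)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(list(chisq = 0, p = 1, observed = o_a, expected = e_a))
  chisq <- (o_a - e_a)^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = o_a, expected = e_a)
}

#' Molecular subtype concordance between PDOs and parental tissue
#'
#' @param cohort data.frame with columns `pdo_subtype` and `tissue_subtype`
#'   (`classical` / `basal_like` / `unknown`).
#' @return list with paired `percent` / `agreements` / `evaluable`, and
#'   per-compartment classical fractions (`pdo_classical`,
#'   `tissue_classical`, each with percent and counts).
#' @export
subtype_concordance <- function(cohort) {
  known <- c("classical", "basal_like")
  paired <- cohort$pdo_subtype %in% known & cohort$tissue_subtype %in% known
  if (!any(paired)) abort("no evaluable subtype pairs")
  agree <- sum(cohort$pdo_subtype[paired] == cohort$tissue_subtype[paired])
  n_pair <- sum(paired)
  comp <- function(v) {
    k <- v %in% known
    list(percent = round_half_up(100 * sum(v[k] == "classical") / sum(k), 1),
         classical = sum(v[k] == "classical"), evaluable = sum(k))
  }
  list(percent = round_half_up(100 * agree / n_pair, 1),
       agreements = agree, evaluable = n_pair,
       pdo_classical = comp(cohort$pdo_subtype),
       tissue_classical = comp(cohort$tissue_subtype))
}

#' Read a cohort table
#'
#' Tab-separated patient records with the controlled vocabularies used by
#' the evaluation functions (see [fixture_cohort()] for the column layout;
#' censoring is encoded by `pfs_event` 0/1).
#'
#' @param path TSV path.
#' @return data.frame of patient records.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("histology_confirmed_pc", "pharmacotyped")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Write a cohort table
#' @param cohort data.frame of patient records.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
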