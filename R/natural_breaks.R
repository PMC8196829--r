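# Jenks natural breaks: exact Fisher optimal 1-D partition.
#
# The classifier partitions a sorted vector into k contiguous classes
# minimizing the total within-class sum of squared deviations, by dynamic
# programming over class boundaries (exact, not the heuristic reallocation
# variant). Among equal-cost partitions the one whose leftmost differing
# break is smallest is chosen, which makes the result deterministic and
# independent of input order. Goodness of variance fit
# GVF = 1 - SDCM/SDAM, where SDAM is the total sum of squared deviations
# about the grand mean and SDCM the within-class sum.

# within-class SSE of sorted x[i..j] for all i in `is` (vectorized), via
# prefix sums S = c(0, cumsum(x)), S2 = c(0, cumsum(x^2))
.class_cost <- function(S, S2, is, j) {
  n_ij <- j - is + 1
  s <- S[j + 1] - S[is]
  pmax(0, (S2[j + 1] - S2[is]) - s^2 / n_ij)
}

#' Jenks natural-breaks classification
#'
#' Exact optimal partition of a numeric vector into `k` contiguous classes of
#' its sorted order, minimizing within-class variance (Fisher's optimal
#' 1-D grouping). Breaks are reported as the maximum of each lower class, so
#' a value equal to a break belongs to the lower class.
#'
#' @param values numeric vector.
#' @param k number of classes (>= 2); requires at least `k` distinct values.
#' @param id optional identifier (e.g. drug id) carried into the model.
#' @return object of class `breaks_model`: `k`, `breaks` (k-1 ascending
#'   interior boundaries), `class_ranges` (k x 2 matrix of observed
#'   lower/upper per class), `counts`, `gvf`, `n`, `assignments` (class index
#'   per input value, in input order).
#' @export
jenks_breaks <- function(values, k, id = NULL) {
  if (length(values) == 0) abort("empty input")
  if (any(!is.finite(values))) abort("values must be finite")
  if (k < 2) abort("k must be >= 2")
  n_distinct <- length(unique(values))
  if (n_distinct < k) {
    abort(sprintf("need at least k = %d distinct values, got %d", k, n_distinct))
  }
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  S <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))

  # D[m, j]: minimal cost of partitioning x[1..j] into m classes
  D <- matrix(Inf, nrow = k, ncol = n)
  D[1, ] <- vapply(seq_len(n), function(j) .class_cost(S, S2, 1L, j), numeric(1))
  for (m in 2:k) {
    for (j in m:n) {
      is <- m:j
      D[m, j] <- min(D[m - 1, is - 1] + .class_cost(S, S2, is, j))
    }
  }
  # Rv[m, i]: minimal cost of partitioning x[i..n] into m classes
  Rv <- matrix(Inf, nrow = k, ncol = n + 1)
  Rv[1, seq_len(n)] <- vapply(seq_len(n), function(i) .class_cost(S, S2, i, n), numeric(1))
  for (m in 2:k) {
    for (i in (n - m + 1):1) {
      es <- i:(n - m + 1)
      Rv[m, i] <- min(.class_cost(S, S2, i, es) + Rv[m - 1, es + 1])
    }
  }

  total <- D[k, n]
  tol <- 1e-9 * (1 + abs(total))
  # greedy front-to-back reconstruction; smallest feasible class end at each
  # step yields the lexicographically smallest break sequence among optima
  ends <- integer(k)
  pos <- 1L
  rem <- total
  for (m in seq_len(k - 1)) {
    left <- k - m
    es <- pos:(n - left)
    costs <- .class_cost(S, S2, pos, es) + Rv[left, es + 1]
    e <- es[which(costs <= rem + tol)[1]]
    ends[m] <- e
    rem <- Rv[left, e + 1]
    pos <- e + 1L
  }
  ends[k] <- n

  starts <- c(1L, ends[-k] + 1L)
  assignments_sorted <- rep(seq_len(k), times = ends - starts + 1L)
  assignments <- integer(n)
  assignments[ord] <- assignments_sorted
  class_ranges <- cbind(lower = x[starts], upper = x[ends])
  sdam <- sum((x - mean(x))^2)
  sdcm <- sum(vapply(seq_len(k), function(m) .class_cost(S, S2, starts[m], ends[m]),
                     numeric(1)))
  structure(
    list(id = id, k = k, breaks = x[ends[-k]], class_ranges = class_ranges,
         counts = ends - starts + 1L, gvf = 1 - sdcm / sdam,
         within_ss = sdcm, n = n, assignments = assignments),
    class = "breaks_model"
  )
}

#' @export
print.breaks_model <- function(x, ...) {
  cat(sprintf("Jenks natural breaks (k = %d, n = %d%s)\n", x$k, x$n,
              if (!is.null(x$id)) paste0(", id = ", x$id) else ""))
  cat(sprintf("  breaks: %s\n", paste(signif(x$breaks, 6), collapse = ", ")))
  cat(sprintf("  GVF: %.4f\n", x$gvf))
  invisible(x)
}

#' Score a value against a frozen breaks model
#'
#' Interval membership against previously fitted breaks: values below the
#' fitted range fall in class 1, above it in class `k`; a value equal to a
#' break belongs to the lower class (breaks are lower-class maxima).
#'
#' @param model a `breaks_model`.
#' @param values numeric vector.
#' @return integer class indices in 1..k.
#' @export
assign_class <- function(model, values) {
  vapply(values, function(v) 1L + sum(v > model$breaks), integer(1))
}

.responder_levels <- c("high", "intermediate", "low")

#' Classify a drug's AUC vector into responder categories
#'
#' Three-class Jenks partition of the per-drug AUC vector of a PDO library:
#' the lowest-AUC class is the high-responder group (score 1), the middle
#' class intermediate (score 2), and the highest-AUC class the low-responder
#' group (score 3). Classification of a library smaller than `n_min` PDOs is
#' refused unless `override = TRUE`.
#'
#' @param library an `auc_library`.
#' @param drug_id drug to classify.
#' @param n_min minimal library size per drug (default 25).
#' @param override allow classification below `n_min` (with a warning).
#' @param k number of responder classes (default 3).
#' @return list with `model` (a `breaks_model`) and `calls` (data.frame
#'   `pdo_id`, `drug_id`, `category`, `score`).
#' @export
classify_drug <- function(library, drug_id, n_min = 25L, override = FALSE, k = 3L) {
  v <- drug_vector(library, drug_id)
  if (length(v) == 0) abort(sprintf("no AUC values for drug '%s'", drug_id))
  if (length(v) < n_min) {
    if (!override) {
      abort(sprintf("drug '%s': library has n = %d PDOs, below the n >= %d rule (set override = TRUE to classify anyway)",
                    drug_id, length(v), n_min))
    }
    warning(sprintf("drug '%s': classifying n = %d PDOs below the n >= %d rule",
                    drug_id, length(v), n_min), call. = FALSE)
  }
  model <- jenks_breaks(v, k = k, id = drug_id)
  calls <- data.frame(
    pdo_id = names(v),
    drug_id = drug_id,
    category = .responder_levels[model$assignments],
    score = model$assignments,
    stringsAsFactors = FALSE
  )
  list(model = model, calls = calls)
}

#' Score new AUC values against a frozen responder model
#'
#' Prospective use: a new PDO is placed into the responder class of a
#' previously fitted per-drug model without re-clustering the library.
#'
#' @param model `breaks_model` fitted by [classify_drug()] (k = 3).
#' @param pdo_id PDO identifiers.
#' @param auc AUC values.
#' @return data.frame `pdo_id`, `drug_id`, `category`, `score`.
#' @export
score_against_breaks <- function(model, pdo_id, auc) {
  cls <- assign_class(model, auc)
  data.frame(pdo_id = pdo_id, drug_id = model$id %||% NA_character_,
             category = .responder_levels[pmin(cls, 3L)], score = cls,
             stringsAsFactors = FALSE)
}

#' Cut-off report for a responder model
#'
#' @param model a fitted 3-class `breaks_model`.
#' @return a one-line character summary of the sensitivity cut-offs.
#' @export
cutoff_report <- function(model) {
  sprintf("%s: high sensitivity AUC < %.1f and low sensitivity > %.1f (GVF %.3f)",
          model$id %||% "drug", model$breaks[1], model$breaks[2], model$gvf)
}

#' Two-class proliferation calls from Ki-67 indices
#'
#' Partitions Ki-67 positivity percentages into low/high proliferative
#' groups, either by a two-class Jenks partition (`"jenks"`) or by the fixed
#' 45% rule (`"fixed45"`: high iff Ki-67 > 45).
#'
#' @param values Ki-67 positivity in percent, within \[0, 100\].
#' @param cutoff_mode `"jenks"` or `"fixed45"`.
#' @return character vector of `"low"` / `"high"` labels.
#' @export
classify_ki67 <- function(values, cutoff_mode = c("jenks", "fixed45")) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (any(!is.finite(values)) || any(values < 0 | values > 100)) {
    abort("Ki-67 values must be percentages in [0, 100]")
  }
  if (cutoff_mode == "fixed45") {
    return(ifelse(values > 45, "high", "low"))
  }
  model <- jenks_breaks(values, k = 2L, id = "ki67")
  c("low", "high")[model$assignments]
}

#' Write per-drug break models and responder calls to TSV
#' @param classified named list of [classify_drug()] results.
#' @param breaks_path,calls_path output TSV paths.
#' @return invisibly, a list of the two paths.
#' @export
write_classification_tsv <- function(classified, breaks_path, calls_path) {
  breaks_df <- do.call(rbind, lapply(classified, function(cl) {
    data.frame(drug_id = cl$model$id, break1 = cl$model$breaks[1],
               break2 = cl$model$breaks[2], gvf = cl$model$gvf,
               n = cl$model$n, stringsAsFactors = FALSE)
  }))
  calls_df <- do.call(rbind, lapply(classified, `[[`, "calls"))
  utils::write.table(breaks_df, breaks_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(calls_df, calls_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(breaks = breaks_path, calls = calls_path))
}
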