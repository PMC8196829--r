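# Regimen prediction: mean-of-scores rule and a hard-margin linear SVM.
#
# The score rule averages the per-drug responder scores (high = 1,
# intermediate = 2, low = 3) of a regimen's screened components; a mean
# <= 2 predicts a sensitive (efficacious) regimen, > 2 a resistant one.
# The SVM alternative fits a maximum-margin separating hyperplane on AUC
# feature vectors of labeled PDOs; the data must be linearly separable
# (no slack) or training errors out.

#' Regimen prediction score for one PDO
#'
#' @param calls data.frame of responder calls for one PDO (columns `drug_id`,
#'   `score`), as produced by [classify_drug()].
#' @param regimen character vector of component drug ids.
#' @param regimen_name label carried into the result.
#' @return list with `pdo_id`, `regimen_name`, `component_scores` (named),
#'   `score` (mean, in \[1, 3\]), and `call` (`"sensitive"` iff score <= 2,
#'   else `"resistant"`).
#' @export
score_regimen <- function(calls, regimen, regimen_name = "regimen") {
  idx <- match(regimen, calls$drug_id)
  if (anyNA(idx)) {
    abort(sprintf("regimen '%s': no responder call for drug '%s'",
                  regimen_name, regimen[which(is.na(idx))[1]]))
  }
  comp <- stats::setNames(as.numeric(calls$score[idx]), regimen)
  score <- mean(comp)
  list(
    pdo_id = if ("pdo_id" %in% names(calls)) unique(calls$pdo_id)[1] else NA_character_,
    regimen_name = regimen_name,
    component_scores = comp,
    score = score,
    call = if (score <= 2) "sensitive" else "resistant"
  )
}

#' Score every regimen for every PDO
#'
#' @param calls data.frame of responder calls (`pdo_id`, `drug_id`, `score`).
#' @param regimens named list regimen -> component drug ids.
#' @return data.frame `pdo_id`, `regimen`, `component_scores` (comma-joined),
#'   `score`, `call`; regimens with missing component calls are skipped.
#' @export
score_all_regimens <- function(calls, regimens) {
  rows <- list()
  for (pdo in unique(calls$pdo_id)) {
    pc <- calls[calls$pdo_id == pdo, , drop = FALSE]
    for (r in names(regimens)) {
      if (!all(regimens[[r]] %in% pc$drug_id)) next
      s <- score_regimen(pc, regimens[[r]], r)
      rows[[length(rows) + 1]] <- data.frame(
        pdo_id = pdo, regimen = r,
        component_scores = paste(s$component_scores, collapse = ","),
        score = s$score, call = s$call, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Hard-margin linear SVM.
#
# Dual problem: max sum(a) - 1/2 sum a_i a_j y_i y_j <x_i, x_j>
# s.t. a >= 0, sum a_i y_i = 0, no upper box (C = infinity).
# Solved by pairwise coordinate ascent (SMO-style working pairs) and then
# refined by solving the KKT equality system on the detected support set, so
# support-vector margins are exactly 1 up to linear-solve precision.
# Unbounded dual growth signals non-separable data and raises an error.

.svm_smo <- function(X, y, max_passes = 4000, tol = 1e-12, alpha_cap = 1e9) {
  n <- nrow(X)
  K <- X %*% t(X)
  a <- rep(0, n)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    f <- as.vector(K %*% (a * y)) # decision values without bias
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        eta <- K[i, i] + K[j, j] - 2 * K[i, j]
        if (eta <= 1e-15) next
        # bias cancels in E_i - E_j
        delta <- y[j] * ((f[i] - y[i]) - (f[j] - y[j])) / eta
        aj_new <- a[j] + delta
        if (y[i] != y[j]) {
          lo <- max(0, a[j] - a[i]); hi <- Inf
        } else {
          lo <- 0; hi <- a[i] + a[j]
        }
        aj_new <- min(max(aj_new, lo), hi)
        step <- aj_new - a[j]
        if (abs(step) < tol * (1 + a[j])) next
        ai_new <- a[i] + y[i] * y[j] * (a[j] - aj_new)
        dai <- ai_new - a[i]; daj <- aj_new - a[j]
        f <- f + K[, i] * (dai * y[i]) + K[, j] * (daj * y[j])
        a[i] <- ai_new; a[j] <- aj_new
        improved <- TRUE
      }
    }
    if (max(a) > alpha_cap) {
      abort("training data are not linearly separable (hard-margin dual is unbounded)")
    }
    if (!improved) break
  }
  a
}

# Solve KKT equalities for a candidate support set: y_i (w.x_i + b) = 1 for
# i in S, w = sum_S a_i y_i x_i, sum_S a_i y_i = 0. Returns NULL if singular
# or any a < -tol.
.svm_kkt_solve <- function(X, y, support) {
  Xs <- X[support, , drop = FALSE]
  ys <- y[support]
  m <- length(support)
  Q <- (ys %o% ys) * (Xs %*% t(Xs))
  A <- rbind(cbind(Q, ys), c(ys, 0))
  rhs <- c(rep(1, m), 0)
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  a <- unname(sol[seq_len(m)])
  b <- unname(sol[m + 1])
  if (any(a < -1e-8)) return(NULL)
  w <- as.vector(t(Xs) %*% (a * ys))
  list(alpha = a, w = w, b = b)
}

#' Train a hard-margin linear SVM on PDO AUC profiles
#'
#' Maximum-margin separating hyperplane for binary outcome labels on AUC
#' feature vectors. Training refuses non-separable data rather than falling
#' back to a soft margin.
#'
#' @param library an `auc_library`.
#' @param labels named vector (`"response"` / `"no_response"`, names = PDO
#'   ids) of clinical outcome labels; at least 2 PDOs per label.
#' @param regimen_name label carried into the model.
#' @param feature_drugs drugs used as features (default: all library drugs).
#' @param standardize z-score features before fitting (default FALSE: AUCs
#'   share one scale).
#' @return object of class `svm_model`: `regimen_name`, `feature_drugs`,
#'   `weights`, `bias`, `support_ids`, `training_ids`, `margin`,
#'   standardization parameters.
#' @export
train_svm <- function(library, labels, regimen_name = "regimen",
                      feature_drugs = colnames(library), standardize = FALSE) {
  ids <- names(labels)
  if (is.null(ids)) abort("labels must be named by PDO id")
  if (!all(ids %in% rownames(library))) {
    abort(sprintf("label PDO '%s' not in library",
                  setdiff(ids, rownames(library))[1]))
  }
  X <- unclass(library)[ids, feature_drugs, drop = FALSE]
  if (anyNA(X)) abort("feature vectors are incomplete for some labeled PDOs")
  y <- ifelse(labels == "response", 1, -1)
  if (length(unique(y)) < 2) abort("both outcome labels must be present")
  center <- rep(0, ncol(X)); scale_ <- rep(1, ncol(X))
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }

  a <- .svm_smo(X, y)
  thresh <- 1e-7 * max(a, 1)
  support <- which(a > thresh)
  fit <- .svm_kkt_solve(X, y, support)
  if (is.null(fit)) {
    # fall back to the SMO solution directly
    w <- as.vector(t(X) %*% (a * y))
    sv <- which(a > thresh)
    b <- mean(y[sv] - X[sv, , drop = FALSE] %*% w)
    fit <- list(alpha = a[sv], w = w, b = b)
    support <- sv
  }
  margins <- y * (as.vector(X %*% fit$w) + fit$b)
  if (any(margins < 1 - 1e-6)) {
    abort("training data are not linearly separable (hard-margin fit infeasible)")
  }
  structure(
    list(regimen_name = regimen_name,
         feature_drugs = feature_drugs,
         weights = stats::setNames(fit$w, feature_drugs),
         bias = fit$b,
         support_ids = ids[support],
         training_ids = ids,
         margin = 1 / sqrt(sum(fit$w^2)),
         center = stats::setNames(center, feature_drugs),
         scale = stats::setNames(scale_, feature_drugs)),
    class = "svm_model"
  )
}

#' Predict outcome for an AUC feature vector
#'
#' @param model an `svm_model`.
#' @param auc_vector named numeric vector covering `model$feature_drugs`.
#' @return `"response"` or `"no_response"`; a decision value of exactly 0 is
#'   reported as `"no_response"` with a boundary warning. The decision value
#'   is attached as attribute `decision`.
#' @export
predict_svm <- function(model, auc_vector) {
  missing <- setdiff(model$feature_drugs, names(auc_vector))
  if (length(missing) > 0) {
    abort(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
  }
  x <- (as.numeric(auc_vector[model$feature_drugs]) - model$center) / model$scale
  d <- sum(model$weights * x) + model$bias
  if (d == 0) {
    warning("point lies exactly on the decision boundary; reporting no_response",
            call. = FALSE)
  }
  structure(if (d > 0) "response" else "no_response", decision = d)
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("hard-margin linear SVM (%s): %d features, %d training PDOs, %d support vectors, margin %.4g\n",
              x$regimen_name, length(x$feature_drugs), length(x$training_ids),
              length(x$support_ids), x$margin))
  invisible(x)
}

#' Write an SVM model to JSON
#' @param model an `svm_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_svm_json <- function(model, path) {
  jsonlite::write_json(
    list(regimen_name = model$regimen_name,
         feature_drugs = model$feature_drugs,
         weights = as.numeric(model$weights),
         bias = model$bias,
         support_ids = model$support_ids,
         training_ids = model$training_ids,
         center = as.numeric(model$center),
         scale = as.numeric(model$scale)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an SVM model from JSON
#' @param path JSON path written by [write_svm_json()].
#' @return an `svm_model`.
#' @export
read_svm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(regimen_name = j$regimen_name,
         feature_drugs = j$feature_drugs,
         weights = stats::setNames(j$weights, j$feature_drugs),
         bias = j$bias,
         support_ids = j$support_ids,
         training_ids = j$training_ids,
         margin = 1 / sqrt(sum(j$weights^2)),
         center = stats::setNames(j$center, j$feature_drugs),
         scale = stats::setNames(j$scale, j$feature_drugs)),
    class = "svm_model"
  )
}
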