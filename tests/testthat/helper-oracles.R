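# Independent oracles and small fixture builders. Oracles deliberately avoid
# the package's own code paths: the Jenks oracle enumerates every contiguous
# partition, the SVM oracle enumerates candidate support subsets, the Fisher
# oracle sums stats::dhyper over the support.

# brute-force minimal within-class SSE over all contiguous k-partitions of
# sorted values; returns list(cost, ends) with lexicographically smallest
# class-end sequence among optima
oracle_jenks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cost_of <- function(lo, hi) {
    xs <- x[lo:hi]
    sum((xs - mean(xs))^2)
  }
  cuts <- utils::combn(n - 1, k - 1) # class end positions (all but last)
  best <- Inf
  best_ends <- NULL
  for (col in seq_len(ncol(cuts))) {
    ends <- c(cuts[, col], n)
    starts <- c(1, ends[-k] + 1)
    cost <- sum(mapply(cost_of, starts, ends))
    if (is.null(best_ends) || cost < best - 1e-12 * (1 + cost)) {
      best <- cost
      best_ends <- ends
    }
  }
  list(cost = best, ends = best_ends)
}

# two-sided Fisher p by summing stats::dhyper over the support
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force hard-margin maximum-margin hyperplane: enumerate support
# subsets, solve the equality KKT system, keep the feasible solution with
# the smallest ||w||. Returns list(w, b) or NULL if non-separable.
oracle_svm <- function(X, y) {
  n <- nrow(X)
  best <- NULL
  best_norm <- Inf
  for (m in 2:min(n, ncol(X) + 1)) {
    subsets <- utils::combn(n, m)
    for (col in seq_len(ncol(subsets))) {
      s <- subsets[, col]
      if (length(unique(y[s])) < 2) next
      Xs <- X[s, , drop = FALSE]
      ys <- y[s]
      Q <- (ys %o% ys) * (Xs %*% t(Xs))
      A <- rbind(cbind(Q, ys), c(ys, 0))
      sol <- tryCatch(solve(A, c(rep(1, m), 0)), error = function(e) NULL)
      if (is.null(sol)) next
      a <- sol[seq_len(m)]
      if (any(a < -1e-9)) next
      w <- as.vector(t(Xs) %*% (a * ys))
      b <- unname(sol[m + 1])
      if (any(y * (X %*% w + b) < 1 - 1e-9)) next
      nw <- sum(w^2)
      if (nw < best_norm - 1e-12) {
        best_norm <- nw
        best <- list(w = w, b = b)
      }
    }
  }
  best
}

# long-format plate for one PDO x drug on a panel, from given per-replicate
# net signals (list per concentration) and a control net signal
make_plate <- function(pdo = "PDO01", drug = "gemcitabine",
                       conc = default_panel()[[1]],
                       net = rep(list(c(1000, 1000)), length(conc)),
                       ctrl_net = c(1000, 1000), background = 100) {
  drug_rows <- do.call(rbind, lapply(seq_along(conc), function(i) {
    data.frame(pdo_id = pdo, drug_id = drug, concentration_molar = conc[i],
               replicate = seq_along(net[[i]]), s1 = background,
               s2 = background + net[[i]], stringsAsFactors = FALSE)
  }))
  ctrl_rows <- data.frame(pdo_id = pdo, drug_id = "CONTROL",
                          concentration_molar = NA_real_,
                          replicate = seq_along(ctrl_net), s1 = background,
                          s2 = background + ctrl_net, stringsAsFactors = FALSE)
  rbind(drug_rows, ctrl_rows)
}

# auc_library straight from a matrix
make_library <- function(m) {
  structure(m, class = c("auc_library", "matrix"))
}

# frozen 3-class responder model with given interior breaks
make_breaks_model <- function(breaks, id = "drug") {
  structure(list(id = id, k = 3L, breaks = breaks,
                 class_ranges = cbind(lower = c(-Inf, breaks),
                                      upper = c(breaks, Inf)),
                 counts = NA, gvf = NA, n = NA, assignments = NULL),
            class = "breaks_model")
}
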