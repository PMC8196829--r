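# Regimen prediction score and hard-margin SVM.

calls_for <- function(scores) {
  data.frame(pdo_id = "PDO01", drug_id = names(scores), score = unname(scores),
             stringsAsFactors = FALSE)
}

test_that("regimen score averages component scores with an inclusive boundary", {
  # all-low responder -> resistant to FOLFIRINOX
  s <- score_regimen(calls_for(c("5-FU" = 3, irinotecan = 3, oxaliplatin = 3)),
                     c("5-FU", "irinotecan", "oxaliplatin"), "FOLFIRINOX")
  expect_equal(s$score, 3)
  expect_equal(s$call, "resistant")

  s <- score_regimen(calls_for(c(gemcitabine = 1, paclitaxel = 1)),
                     c("gemcitabine", "paclitaxel"))
  expect_equal(s$score, 1)
  expect_equal(s$call, "sensitive")

  # boundary: (1 + 3) / 2 = 2 -> sensitive
  s <- score_regimen(calls_for(c(gemcitabine = 1, paclitaxel = 3)),
                     c("gemcitabine", "paclitaxel"))
  expect_equal(s$score, 2)
  expect_equal(s$call, "sensitive")

  expect_error(score_regimen(calls_for(c(gemcitabine = 1)),
                             c("gemcitabine", "paclitaxel"), "gem/nab-p"),
               "no responder call for drug 'paclitaxel'")
})

test_that("score rule holds on every component combination (3^4 cases)", {
  grid <- expand.grid(a = 1:3, b = 1:3, c = 1:3, d = 1:3)
  for (i in seq_len(nrow(grid))) {
    sc <- as.numeric(grid[i, ])
    s <- score_regimen(calls_for(stats::setNames(sc, paste0("d", 1:4))),
                       paste0("d", 1:4))
    expect_equal(s$score, mean(sc))
    expect_gte(s$score, 1)
    expect_lte(s$score, 3)
    expect_equal(s$call, if (mean(sc) <= 2) "sensitive" else "resistant")
    # permutation invariance of components
    perm <- sample(4)
    s2 <- score_regimen(calls_for(stats::setNames(sc[perm], paste0("d", perm))),
                        paste0("d", 1:4))
    expect_equal(s2$score, s$score)
  }
})

test_that("symmetric 1-D pair gives the mid-point hyperplane", {
  lib <- make_library(matrix(c(-1, 1), ncol = 1,
                             dimnames = list(c("A", "B"), "d")))
  m <- train_svm(lib, c(A = "no_response", B = "response"), feature_drugs = "d")
  expect_equal(unname(m$weights), 1, tolerance = 1e-9)
  expect_equal(m$bias, 0, tolerance = 1e-9)
  expect_setequal(m$support_ids, c("A", "B"))

  expect_equal(as.character(predict_svm(m, c(d = 2))), "response")
  expect_warning(p0 <- predict_svm(m, c(d = 0)), "boundary")
  expect_equal(as.character(p0), "no_response")
  expect_error(predict_svm(m, c(e = 1)), "missing feature")
})

test_that("SVM equals the brute-force maximum-margin oracle on small sets", {
  set.seed(505)
  for (case in 1:30) {
    n <- sample(4:8, 1)
    d <- sample(1:3, 1)
    n_pos <- sample(2:(n - 2), 1)
    y <- c(rep(1, n_pos), rep(-1, n - n_pos))
    X <- matrix(stats::rnorm(n * d), n, d) + outer(y, rep(2.5, d))
    rownames(X) <- sprintf("P%02d", 1:n)
    colnames(X) <- paste0("f", 1:d)
    oracle <- oracle_svm(X, y)
    if (is.null(oracle)) next # rare non-separable draw
    lib <- make_library(X)
    labels <- stats::setNames(ifelse(y > 0, "response", "no_response"), rownames(X))
    m <- train_svm(lib, labels, feature_drugs = colnames(X))
    expect_equal(unname(m$weights), oracle$w, tolerance = 1e-6)
    expect_equal(m$bias, oracle$b, tolerance = 1e-6)
    # hard-margin invariants: all margins >= 1, support margins == 1
    margins <- y * (X %*% oracle$w + oracle$b)
    got_margins <- y * (X %*% m$weights + m$bias)
    expect_true(all(got_margins >= 1 - 1e-6))
    expect_true(all(abs(got_margins[rownames(X) %in% m$support_ids] - 1) < 1e-5))
  }
})

test_that("feature scaling flips no predicted label", {
  set.seed(606)
  n <- 8
  y <- rep(c(1, -1), each = 4)
  X <- matrix(stats::rnorm(n * 2), n, 2) + outer(y, c(3, 3))
  rownames(X) <- sprintf("P%d", 1:n)
  colnames(X) <- c("f1", "f2")
  labels <- stats::setNames(ifelse(y > 0, "response", "no_response"), rownames(X))
  m1 <- train_svm(make_library(X), labels, feature_drugs = colnames(X))
  m2 <- train_svm(make_library(X * 10), labels, feature_drugs = colnames(X))
  test_pts <- matrix(stats::rnorm(20), 10, 2, dimnames = list(NULL, colnames(X)))
  for (i in 1:10) {
    p1 <- as.character(predict_svm(m1, test_pts[i, ]))
    p2 <- as.character(predict_svm(m2, test_pts[i, ] * 10))
    expect_equal(p1, p2)
  }
  expect_equal(m2$margin, 10 * m1$margin, tolerance = 1e-6)
})

test_that("non-separable or degenerate training data error out", {
  lib <- make_library(matrix(c(-1, -0.5, 0.5, 1), ncol = 1,
                             dimnames = list(sprintf("Q%d", 1:4), "d")))
  labels <- stats::setNames(c("response", "no_response", "response", "no_response"),
                            rownames(lib))
  expect_error(train_svm(lib, labels, feature_drugs = "d"), "not linearly separable")
  expect_error(train_svm(lib, stats::setNames(rep("response", 4), rownames(lib)),
                         feature_drugs = "d"), "both outcome labels")
})

test_that("a held-out response-archetype PDO is predicted as response", {
  # train on synthetic AUC profiles labeled by true gem/nab-p sensitivity;
  # hold out one truly sensitive PDO per seed
  hits <- 0; tries <- 0
  for (seed in 1:20) {
    cfg <- generator_config(n_pdos = 12, seed = seed)
    g <- generate_plates(cfg)
    lib <- build_library(lapply(compute_viability_all(g$wells, cfg$panel),
                                compute_auc))
    comp <- c("gemcitabine", "paclitaxel")
    sens <- vapply(rownames(lib), function(p) {
      mean(g$truth$true_score[g$truth$pdo_id == p & g$truth$drug_id %in% comp]) <= 2
    }, logical(1))
    # hold out a PDO drawn from the response archetype for both components
    archetypal <- vapply(rownames(lib), function(p) {
      all(g$truth$true_score[g$truth$pdo_id == p & g$truth$drug_id %in% comp] == 1)
    }, logical(1))
    hold <- which(archetypal)[1]
    if (is.na(hold)) next
    train_ids <- rownames(lib)[-hold]
    if (length(unique(sens[-hold])) < 2) next
    labels <- stats::setNames(ifelse(sens[train_ids], "response", "no_response"),
                              train_ids)
    m <- tryCatch(train_svm(lib, labels, regimen_name = "gem/nab-p"),
                  error = function(e) NULL)
    if (is.null(m)) next # non-separable draw
    tries <- tries + 1
    pred <- predict_svm(m, unclass(lib)[hold, ])
    if (as.character(pred) == "response") hits <- hits + 1
  }
  expect_gte(tries, 10)
  expect_gte(hits / tries, 0.9)
})

test_that("SVM models round-trip through JSON", {
  lib <- make_library(matrix(c(-2, -1, 1, 2), ncol = 1,
                             dimnames = list(sprintf("P%d", 1:4), "d")))
  labels <- stats::setNames(c("no_response", "no_response", "response", "response"),
                            rownames(lib))
  m <- train_svm(lib, labels, feature_drugs = "d", regimen_name = "FOLFIRINOX")
  path <- withr::local_tempfile(fileext = ".json")
  write_svm_json(m, path)
  back <- read_svm_json(path)
  expect_equal(back$weights, m$weights)
  expect_equal(back$bias, m$bias)
  expect_equal(back$support_ids, m$support_ids)
  expect_equal(as.character(predict_svm(back, c(d = 0.6))),
               as.character(predict_svm(m, c(d = 0.6))))
})
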