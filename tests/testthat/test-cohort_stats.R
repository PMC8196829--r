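# Cohort evaluation statistics, cross-checked against stats/survival.

test_that("RECIST best response maps to tumor control", {
  expect_equal(tumor_control(c("CR", "PR", "SD")), rep("response", 3))
  expect_equal(tumor_control("PD"), "no_response")
  expect_equal(tumor_control("not_available"), "not_available")
  expect_error(tumor_control("XX"), "invalid RECIST")
})

test_that("pharmacotyping efficacy reports stratum proportions and counts", {
  co <- fixture_cohort()
  overall <- pharmacotyping_efficacy(co)
  expect_equal(overall$percent, 63.6)
  expect_equal(overall$numerator, 28)
  expect_equal(overall$denominator, 44)

  # a stratum with zero successes
  zero <- pharmacotyping_efficacy(
    co, co$sampling_method == "us_biopsy" & co$biopsy_site == "primary" &
      !co$pharmacotyped & co$histology_confirmed_pc)
  expect_equal(zero$percent, 0)

  expect_error(pharmacotyping_efficacy(co, rep(FALSE, nrow(co))), "empty stratum")
  # ordering invariance
  shuffled <- co[rev(seq_len(nrow(co))), ]
  expect_equal(pharmacotyping_efficacy(shuffled)$percent, overall$percent)
})

test_that("prediction accuracy excludes unavailable outcomes and counts them", {
  co <- fixture_cohort()
  pr <- fixture_predictions()
  pred <- data.frame(patient_id = pr$patient_id, call = pr$call,
                     outcome = pr$outcome, stringsAsFactors = FALSE)
  expect_equal(prediction_accuracy(co, pred, pr$line == "second")$percent, 80.0)
  expect_equal(prediction_accuracy(co, pred, pr$line == "pretreated")$percent, 40.0)

  all_match <- data.frame(patient_id = co$patient_id[1:6],
                          call = rep(c("sensitive", "resistant"), 3),
                          outcome = rep(c("response", "no_response"), 3))
  expect_equal(prediction_accuracy(co, all_match)$percent, 100.0)

  with_na <- rbind(all_match,
                   data.frame(patient_id = co$patient_id[7], call = "sensitive",
                              outcome = "not_available"))
  acc <- prediction_accuracy(co, with_na)
  expect_equal(acc$excluded, 1)
  expect_equal(acc$evaluated, 6)

  only_na <- data.frame(patient_id = co$patient_id[1], call = "sensitive",
                        outcome = "not_available")
  expect_error(prediction_accuracy(co, only_na), "no evaluable")
})

test_that("exact Fisher test matches the reference implementation", {
  expect_equal(round(fisher_exact_two_sided(matrix(c(11, 9, 3, 5), 2)), 4), 0.6776)
  expect_equal(round(fisher_exact_two_sided(matrix(c(11, 8, 3, 8), 2)), 4), 0.1424)
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_error(fisher_exact_two_sided(matrix(0, 2, 2)), "all-zero")

  set.seed(707)
  for (case in 1:100) {
    tab <- matrix(stats::rpois(4, sample(1:15, 1)), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # symmetry under swapping rows or columns
    expect_equal(fisher_exact_two_sided(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(tab[, 2:1]), p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney is exact for small samples", {
  expect_equal(mann_whitney_two_sided(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(mann_whitney_two_sided(c(1, 2), c(10, 20)), 1 / 3, tolerance = 1e-12)
  set.seed(808)
  for (case in 1:20) {
    x <- stats::rnorm(9)
    y <- stats::rnorm(5, mean = stats::runif(1, -1, 1))
    expect_equal(mann_whitney_two_sided(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(mann_whitney_two_sided(numeric(0), 1), "non-empty")
})

test_that("Kaplan-Meier matches hand product-limit and survival::survfit", {
  # all events: empirical survival, median at S(t) <= 0.5
  km <- km_curve(1:5, rep(1, 5))
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)

  # worked censored example: censor at 1 and 4, events at 2, 3, 5
  km <- km_curve(c(1, 2, 3, 4, 5), c(0, 1, 1, 0, 1))
  expect_equal(km$surv[km$time == 2], 0.75)
  expect_equal(km$surv[km$time == 3], 0.50)
  expect_equal(km$median, 3)

  # all censored: S == 1, median undefined
  km <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_length(km$time, 0)
  expect_true(is.na(km$median))

  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
  expect_error(km_curve(numeric(0), integer(0)), "empty")

  skip_if_not_installed("survival")
  set.seed(909)
  for (case in 1:10) {
    t <- sample(1:40, 20, replace = TRUE)
    e <- stats::rbinom(20, 1, 0.7)
    if (sum(e) == 0) next
    km <- km_curve(t, e)
    ref <- survival::survfit(survival::Surv(t, e) ~ 1)
    ref_surv <- summary(ref, times = km$time)$surv
    expect_equal(km$surv, ref_surv, tolerance = 1e-9)
  }
})

test_that("log-rank test matches hand computation and survival::survdiff", {
  ident <- logrank_test(c(3, 5, 8), c(1, 1, 1), c(3, 5, 8), c(1, 1, 1))
  expect_equal(ident$chisq, 0)
  expect_equal(ident$p, 1.0)

  # fully separated event times: hand O-E/V oracle over the 6 event times
  a <- c(1, 2, 3); b <- c(101, 102, 103)
  lr <- logrank_test(a, c(1, 1, 1), b, c(1, 1, 1))
  # at times 1,2,3 group A has d=1 with n_a/n = 3/6, 2/5, 1/4; afterwards
  # A is exhausted so E contributions stop
  e_a <- 3 / 6 + 2 / 5 + 1 / 4
  v <- (3 / 6) * (3 / 6) + (2 / 5) * (3 / 5) + (1 / 4) * (3 / 4)
  expect_equal(lr$observed, 3)
  expect_equal(lr$expected, e_a, tolerance = 1e-12)
  expect_equal(lr$chisq, (3 - e_a)^2 / v, tolerance = 1e-12)

  expect_warning(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(1, 1)), "zero events")

  skip_if_not_installed("survival")
  set.seed(1010)
  for (case in 1:10) {
    t1 <- sample(1:50, 15, replace = TRUE); e1 <- stats::rbinom(15, 1, 0.8)
    t2 <- sample(1:50, 15, replace = TRUE) + 5; e2 <- stats::rbinom(15, 1, 0.8)
    if (sum(e1) == 0 || sum(e2) == 0) next
    lr <- logrank_test(t1, e1, t2, e2)
    ref <- survival::survdiff(survival::Surv(c(t1, t2), c(e1, e2)) ~
                                rep(1:2, each = 15))
    expect_equal(lr$chisq, ref$chisq, tolerance = 1e-9)
  }
})

test_that("label permutation symmetrizes the log-rank statistic", {
  set.seed(1111)
  t <- sample(1:30, 16, replace = TRUE)
  e <- stats::rbinom(16, 1, 0.8)
  lr1 <- logrank_test(t[1:8], e[1:8], t[9:16], e[9:16])
  lr2 <- logrank_test(t[9:16], e[9:16], t[1:8], e[1:8])
  expect_equal(lr1$chisq, lr2$chisq, tolerance = 1e-9)
  expect_equal(lr1$p, lr2$p, tolerance = 1e-9)
})

test_that("subtype concordance reports paired and per-compartment fractions", {
  co <- fixture_cohort()
  sc <- subtype_concordance(co)
  expect_equal(sc$percent, 76.2)
  expect_equal(sc$agreements, 16)
  expect_equal(sc$evaluable, 21)
  expect_equal(sc$pdo_classical$percent, 76.0)
  expect_equal(sc$tissue_classical$percent, 85.7)

  toy <- data.frame(pdo_subtype = c("classical", "basal_like"),
                    tissue_subtype = c("classical", "basal_like"))
  expect_equal(subtype_concordance(toy)$percent, 100.0)
  none <- data.frame(pdo_subtype = "unknown", tissue_subtype = "classical")
  expect_error(subtype_concordance(none), "no evaluable")
})

test_that("cohort TSV round-trips", {
  co <- fixture_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$patient_id, co$patient_id)
  expect_equal(back$pharmacotyped, co$pharmacotyped)
  expect_equal(back$pfs_days, co$pfs_days)
})
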