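test_that("cross-validation folds are disjoint, covering and size-balanced", {
  f <- make_cv_folds(193, 10, seed = 1)
  sizes <- as.integer(table(f))
  expect_equal(sort(sizes, decreasing = TRUE), c(20, 20, 20, rep(19, 7)))
  expect_equal(length(f), 193)
  # leave-one-out
  expect_equal(sort(as.integer(table(make_cv_folds(10, 10, seed = 2)))),
               rep(1L, 10))
  # determinism
  expect_identical(make_cv_folds(50, 5, seed = 3),
                   make_cv_folds(50, 5, seed = 3))
  expect_error(make_cv_folds(5, 10), "exceed")
})

test_that("stratified folds preserve group proportions within one subject", {
  lab <- rep(c("A", "B"), c(60, 40))
  f <- make_cv_folds(100, 10, seed = 4, stratify_by = lab)
  tab <- table(lab, f)
  expect_true(all(abs(tab["A", ] - 6) <= 1))
  expect_true(all(abs(tab["B", ] - 4) <= 1))
  expect_true(all(abs(as.integer(table(f)) - 10) <= 1))
})

test_that("repeated CV is perfect on separable groups and degenerate cases flag", {
  coh <- generate_cohort(c(10, 10, 10, 10), n_sites = 1, seed = 5)
  ft <- generate_feature_table(coh, effect_spec(n_regions = 4, beta_dx = 10),
                               seed = 5)
  cv <- run_repeated_cv(ft, coh, "two_group", n_repetitions = 3, seed = 6)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$sd_accuracy, 0)
  # out-of-fold predictions exist exactly once per subject per repetition
  expect_false(anyNA(cv$predictions))
  expect_equal(dim(cv$predictions), c(3, 40))

  cv1 <- run_repeated_cv(ft, coh, "two_group", n_repetitions = 1, seed = 6)
  expect_equal(cv1$sd_accuracy, 0)
  expect_true(cv1$degenerate_sd)
})

test_that("null-label CV accuracy is at chance", {
  # permuted null: features carry no signal
  coh <- generate_cohort(c(25, 25, 25, 25), n_sites = 1, seed = 7)
  ft <- generate_feature_table(coh, effect_spec(n_regions = 2), seed = 7)
  cv <- run_repeated_cv(ft, coh, "two_group", n_repetitions = 10, seed = 8)
  # repetitions share the same null labeling, so the mean accuracy
  # concentrates only at the single-split binomial scale:
  # 0.5 +/- 2.576 * 0.5 / sqrt(100)
  expect_gt(cv$mean_accuracy, 0.371)
  expect_lt(cv$mean_accuracy, 0.629)
})

test_that("most frequent scenario picks the modal prediction vector", {
  runs <- structure(list(
    predictions = rbind(c("A", "B"), c("A", "A"), c("A", "B"), c("B", "B")),
    scenario_keys = c("A|B", "A|A", "A|B", "B|B")), class = "cv_run_set")
  sc <- most_frequent_scenario(runs)
  expect_equal(sc$key, "A|B")
  expect_equal(sc$count, 2)
  expect_equal(sc$repetition, 1)
  expect_equal(sc$predictions, c("A", "B"))

  # tie broken by earliest first occurrence
  runs2 <- structure(list(
    predictions = rbind(c("B", "B"), c("A", "B"), c("B", "B"), c("A", "B")),
    scenario_keys = c("B|B", "A|B", "B|B", "A|B")), class = "cv_run_set")
  expect_equal(most_frequent_scenario(runs2)$key, "B|B")

  # all identical
  runs3 <- structure(list(predictions = rbind(c("A", "A"), c("A", "A")),
                          scenario_keys = c("A|A", "A|A")),
                     class = "cv_run_set")
  expect_equal(most_frequent_scenario(runs3)$count, 2)

  # deterministic separable fixture: a single scenario across repetitions
  coh <- generate_cohort(c(8, 8, 8, 8), n_sites = 1, seed = 9)
  ft <- generate_feature_table(coh, effect_spec(n_regions = 4, beta_dx = 10),
                               seed = 9)
  cv <- run_repeated_cv(ft, coh, "two_group", n_repetitions = 5, seed = 10)
  expect_equal(length(unique(cv$scenario_keys)), 1)
  expect_equal(most_frequent_scenario(cv)$count, 5)
})

test_that("two-group confusion summary reproduces the printed arithmetic", {
  truth <- c(rep("ASD", 106), rep("TD", 84))
  pred <- c(rep("ASD", 103), rep("TD", 3), rep("ASD", 7), rep("TD", 77))
  cs <- confusion_summary(truth, pred, "two_group")
  expect_equal(unname(cs$counts), c(103, 77, 3, 7))  # TP TN FN FP
  expect_equal(cs$sensitivity, 97.17)
  expect_equal(cs$specificity, 91.67)
  # printed count -> percentage conversions at n = 193
  truth193 <- c(truth, rep("ASD", 2), "TD")
  pred193 <- c(pred, rep("TD", 2), "ASD")
  cs193 <- confusion_summary(truth193, pred193, "two_group")
  expect_equal(unname(cs193$percent[c("TP", "TN")]), c(53.37, 39.90))
  # paper-labeled rendering swaps the error labels only
  expect_equal(unname(cs$paper_labels[c("FN", "FP")]),
               unname(cs$counts[c("FP", "FN")]))
  # accuracy recomputable from the counts exactly
  expect_equal(cs$accuracy,
               round_half_up(100 * (cs$counts[["TP"]] + cs$counts[["TN"]]) /
                               cs$n, 2))
  # perfect prediction
  perf <- confusion_summary(truth, truth, "two_group")
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)
  expect_error(confusion_summary(c("X"), c("ASD"), "two_group"), "labels")
})

test_that("four-group confusion tensor reproduces the printed arithmetic", {
  mk <- function(n, lab) rep(lab, n)
  truth <- c(mk(52, "ASD_M"), mk(3, "ASD_M"),     # 55 ASD males, 3 errors
             mk(54, "ASD_F"), mk(1, "ASD_F"),     # 55 ASD females, 1 error
             mk(39, "TD_M"), mk(4, "TD_M"),       # 43 TD males, 4 errors
             mk(38, "TD_F"), mk(2, "TD_F"))       # 40 TD females, 2 errors
  pred <- c(mk(52, "ASD_M"), mk(3, "TD_M"),
            mk(54, "ASD_F"), mk(1, "TD_F"),
            mk(39, "TD_M"), mk(4, "ASD_M"),
            mk(38, "TD_F"), mk(2, "ASD_F"))
  cs <- confusion_summary(truth, pred, "four_group")
  expect_equal(unname(cs$counts[c("TP_M", "TN_M", "TP_F", "TN_F")]),
               c(52, 39, 54, 38))
  expect_equal(cs$sensitivity, 96.36)  # (52 + 54) / 110
  expect_equal(cs$specificity, 92.77)  # (39 + 38) / 83
  expect_equal(unname(cs$percent[c("TN_M", "TP_F")]), c(20.21, 27.98))
  expect_equal(sum(cs$counts), cs$n)  # counts partition the subjects
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(53.365, 2), 53.37)
})
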