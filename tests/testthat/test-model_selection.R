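test_that("confusion matrices tally calls against labels", {
  rule <- structure(list(beta = 0.1, cut = 0, policy = "td-quantile"),
                    class = "threshold_rule")
  # hand tally around the cut
  scores <- c(-2, -1, 0.5, 1, -0.3, 2)
  labels <- c("TD", "ASD", "ASD", "ASD", "TD", "TD")
  cm <- confusion_at_threshold(scores, labels, rule)
  expect_equal(unlist(cm[c("TP", "FP", "FN", "TN")]),
               c(TP = 2, FP = 1, FN = 1, TN = 2))
  # all above, all ASD
  cm2 <- confusion_at_threshold(c(1, 2, 3), rep("ASD", 3), rule)
  expect_equal(unlist(cm2[c("TP", "FP", "FN", "TN")]),
               c(TP = 3, FP = 0, FN = 0, TN = 0))
  # flipping labels swaps TP<->FP and FN<->TN
  flipped <- confusion_at_threshold(scores,
                                    ifelse(labels == "ASD", "TD", "ASD"),
                                    rule)
  expect_equal(flipped$FP, cm$TP)
  expect_equal(flipped$TP, cm$FP)
  expect_equal(flipped$TN, cm$FN)
  expect_equal(flipped$FN, cm$TN)
  expect_error(confusion_at_threshold(numeric(0), character(0), rule),
               "no scores")
})

test_that("LOOCV produces one out-of-fold decision per sample per beta", {
  pan <- random_panel(12, 12, 3, seed = 1, effect = 1.5)
  rep <- run_loocv(pan, classifier_spec("FDA"), betas = c(0.05, 0.2))
  expect_equal(nrow(rep$rows), 2)
  for (i in 1:2) {
    row <- rep$rows[i, ]
    expect_equal(row$TP + row$FN, 12)  # ASD cohort size
    expect_equal(row$FP + row$TN, 12)  # TD cohort size
  }
  # threshold monotonicity carries over to the CV confusion counts
  expect_gte(rep$rows$TP[2], rep$rows$TP[1])
  expect_gte(rep$rows$FP[2], rep$rows$FP[1])
  expect_error(run_loocv(pan, classifier_spec("CART")), "fitted-only")
})

test_that("LOOCV is order-invariant and leak-free", {
  pan <- random_panel(10, 10, 2, seed = 2, effect = 1)
  rep1 <- run_loocv(pan, classifier_spec("LR"), betas = 0.1)
  perm <- with_seed(3, sample(20))
  rep2 <- run_loocv(subset_panel(pan, samples = perm),
                    classifier_spec("LR"), betas = 0.1)
  expect_equal(rep1$rows$TP, rep2$rows$TP)
  expect_equal(rep1$rows$TN, rep2$rows$TN)

  # flipping the held-out sample's own label cannot change its prediction
  for (seed in 1:20) {
    pan <- random_panel(8, 8, 2, seed = 100 + seed, effect = 1)
    i <- with_seed(seed, sample(16, 1))
    before <- focmpanel:::loocv_predict_one(pan, classifier_spec("FDA"), i,
                                            c(0.05, 0.2))
    flipped <- pan
    flipped$labels[i] <- ifelse(pan$labels[i] == "ASD", "TD", "ASD")
    after <- focmpanel:::loocv_predict_one(flipped, classifier_spec("FDA"),
                                           i, c(0.05, 0.2))
    expect_identical(before$calls, after$calls)
    expect_identical(before$score, after$score)
  }
})

test_that("exhaustive search enumerates and wins against recomputation", {
  pan <- random_panel(20, 20, 6, seed = 4, effect = 1,
                      informative = c(1, 2))
  spec <- classifier_spec("FDA")
  res <- exhaustive_subset_search(pan, spec, 2)
  expect_equal(res$n_evaluated, choose(6, 2))
  # independent recomputation loop over every pair via the public fitters
  vars <- panel_variables(pan)
  for (pair in asplit(combn(vars, 2), 2)) {
    cs <- c_statistic(fit_score_densities(
      project(pan, fit_fda_direction(pan, pair)), pan$labels))
    expect_lte(cs, res$c_statistic + 1e-9)
  }
  # k = 1 agrees with the best univariate fit
  res1 <- exhaustive_subset_search(pan, spec, 1)
  uni <- vapply(vars, function(v) {
    c_statistic(fit_score_densities(project(pan, fit_univariate(pan, v)),
                                    pan$labels))
  }, numeric(1))
  expect_equal(res1$best_subset, names(which.max(uni)))
  expect_equal(res1$c_statistic, max(uni), tolerance = 1e-9)
  # k = p evaluates the single full combination
  resp <- exhaustive_subset_search(pan, spec, 6)
  expect_equal(resp$n_evaluated, 1)
  expect_error(exhaustive_subset_search(pan, spec, 7), "between")
  expect_error(exhaustive_subset_search(pan, classifier_spec("PCA"), 2),
               "FDA and LR")
})

test_that("exhaustive search never loses to random hand-picked subsets", {
  pan <- random_panel(20, 20, 8, seed = 5, effect = 0.8,
                      informative = c(1, 3))
  spec <- classifier_spec("FDA")
  res <- exhaustive_subset_search(pan, spec, 3)
  for (r in 1:100) {
    sub <- with_seed(1000 + r, sample(panel_variables(pan), 3))
    cs <- focmpanel:::fitted_c_for_subset(pan, spec, sort(sub))
    expect_lte(cs, res$c_statistic + 1e-9)
  }
})

test_that("saturation is detected where the curve flattens", {
  # one variable separates perfectly: saturation at k = 1
  pan <- separable_panel(20, 20, p = 4, seed = 6, margin = 6)
  sat <- saturation_curve(pan, classifier_spec("FDA"), k_max = 3)
  expect_equal(sat$saturation_k, 1)
  expect_false(sat$decreasing)
  # delta = 0 only saturates on an exact non-increase
  sat0 <- saturation_curve(pan, classifier_spec("FDA"), k_max = 3, delta = 0)
  inc <- diff(sat0$curve$c_statistic)
  expected_k <- if (any(inc < 0)) which(inc < 0)[1] else NA_integer_
  expect_equal(sat0$saturation_k, expected_k)
})

test_that("external validation reports TP/FN on case-only cohorts", {
  pan <- random_panel(30, 30, 4, seed = 7, effect = 1.5)
  spec <- classifier_spec("FDA")
  # validation = copy of the training ASD subset: determinism bounds
  val <- subset_panel(pan, samples = pan$labels == "ASD")
  ev <- external_validation(pan, val, spec)
  expect_true(all(ev$rows$TP + ev$rows$FN == 30))
  # TP non-decreasing in beta (same fitted model, looser cut)
  expect_true(all(diff(ev$rows$TP) >= 0))
  # identical samples, identical model: TP rate >= training fitted rate
  fc <- fit_classifier(pan, spec)
  train_scores <- project(pan, fc$model)[pan$labels == "ASD"]
  for (b in seq_along(ev$rows$beta)) {
    rule <- fc$rules[[sprintf("%.2f", ev$rows$beta[b])]]
    fitted_tp <- sum(classify_scores(train_scores, rule) == "ASD")
    expect_equal(ev$rows$TP[b], fitted_tp)
  }
  # a cohort containing TD labels is rejected
  expect_error(external_validation(pan, pan, spec), "case-only")
  # UNKNOWN labels are scored as cases
  unk <- val
  unk$labels <- rep("UNKNOWN", 30)
  ev2 <- external_validation(pan, unk, spec)
  expect_equal(ev2$rows$TP, ev$rows$TP)
})

test_that("evaluation reports round-trip through tidy CSV", {
  pan <- random_panel(12, 12, 3, seed = 8, effect = 1)
  rep <- run_loocv(pan, classifier_spec("FDA"), betas = c(0.05, 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep$rows, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("classifier", "variables", "beta", "TP", "FP", "FN",
                     "TN", "c_statistic"))
  expect_equal(back$TP, rep$rows$TP)
})
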