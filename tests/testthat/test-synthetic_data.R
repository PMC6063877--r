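test_that("cohort generation is reproducible and strictly positive", {
  cfg <- synthetic_config(seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$panel$values, b$panel$values)
  expect_identical(a$panel$labels, b$panel$labels)
  expect_true(all(a$panel$values > 0))
  expect_equal(n_samples(a$panel), 83 + 76)
  expect_equal(panel_variables(a$panel), focm_variable_ids())
  # different seeds give different draws
  expect_false(identical(generate_cohort(synthetic_config(seed = 6))$panel$values,
                         a$panel$values))
})

test_that("ratio variables are computed from their parents", {
  cfg <- synthetic_config(seed = 7)
  pan <- generate_cohort(cfg)$panel
  v <- pan$values
  expect_equal(v[, "x4"], v[, "x2"] / v[, "x3"], tolerance = 1e-12)
  expect_equal(v[, "x21"], v[, "x19"] / v[, "x20"], tolerance = 1e-12)
  expect_equal(v[, "x22"], 100 * v[, "x12"] / v[, "x10"], tolerance = 1e-12)
  expect_equal(v[, "x13"], v[, "x11"] / v[, "x12"], tolerance = 1e-12)
  expect_equal(v[, "x14"], v[, "x10"] / v[, "x12"], tolerance = 1e-12)
})

test_that("configs validate their structure", {
  expect_error(synthetic_config(rho = 1), "rho")
  expect_error(synthetic_config(informative = c("x4", "x99")), "informative")
  expect_error(synthetic_config(effects = c(x4 = 1)), "effects")
  # a panel without a ratio's parents is rejected
  expect_error(synthetic_config(variables = c("x4", "x8", "x12"),
                                informative = "x8",
                                effects = c(x8 = -1)),
               "parents")
})

test_that("a zero-effect cohort carries no class signal", {
  cfg <- synthetic_config(n_asd = 40, n_td = 40, seed = 11,
                          effects = c(x4 = 0, x8 = 0, x12 = 0, x21 = 0,
                                      x22 = 0))
  truth <- generate_cohort(cfg)$truth
  expect_equal(truth$mahalanobis, 0)
  # cross-validated separation hovers at chance over replicates
  cs <- vapply(1:5, function(r) {
    cfg_r <- synthetic_config(n_asd = 40, n_td = 40, seed = 100 + r,
                              effects = c(x4 = 0, x8 = 0, x12 = 0,
                                          x21 = 0, x22 = 0))
    pan <- generate_cohort(cfg_r)$panel
    run_loocv(pan, classifier_spec("FDA", subset = c("x1", "x8", "x12")),
              betas = 0.05)$cv_c
  }, numeric(1))
  expect_lt(abs(mean(cs) - 0.5), 0.1)
})

test_that("validation cohorts come from the ASD distribution", {
  cfg <- synthetic_config(seed = 12, n_validation = 2000)
  val <- generate_validation_cohort(cfg)
  expect_true(all(val$labels == "ASD"))
  expect_equal(n_samples(val), 2000)
  truth <- generate_cohort(cfg)$truth
  # informative log means sit within 4 standard errors of the ASD truth
  for (v in c("x8", "x12")) {
    se <- cfg$sdlog / sqrt(2000)
    expect_lt(abs(mean(log(val$values[, v])) - truth$mu_asd[v]), 4 * se)
  }
  # n_validation = 0 gives an empty, header-compatible panel
  empty <- generate_validation_cohort(synthetic_config(seed = 1,
                                                       n_validation = 0))
  expect_equal(n_samples(empty), 0)
  expect_equal(panel_variables(empty), focm_variable_ids())
  # a distribution shift moves only non-informative variables
  shifted <- generate_validation_cohort(cfg, shift = 2)
  expect_gt(mean(log(shifted$values[, "x1"])) - mean(log(val$values[, "x1"])),
            0.4)
  expect_lt(abs(mean(log(shifted$values[, "x8"])) -
                  mean(log(val$values[, "x8"]))), 0.1)
})

test_that("neighboring seeds draw from the same distribution", {
  # two-sample t test on FDA scores across seeds should rarely reject
  cfg1 <- synthetic_config(seed = 21)
  fc <- fit_classifier(generate_cohort(cfg1)$panel, classifier_spec("FDA"),
                       betas = 0.05)
  rejections <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    v1 <- generate_validation_cohort(synthetic_config(seed = 300 + r))
    v2 <- generate_validation_cohort(synthetic_config(seed = 301 + r))
    pval <- t.test(project(v1, fc$model), project(v2, fc$model))$p.value
    rejections <- rejections + (pval < 0.01)
  }
  expect_lte(rejections, 2)  # ~1% rejection rate expected under the null
})

test_that("large-cohort covariance matches the log-normal moment map", {
  cfg <- synthetic_config(n_asd = 2, n_td = 10000, seed = 13)
  pan <- generate_cohort(cfg)$panel
  td <- pan$values[pan$labels == "TD", cfg$base_vars]
  emp <- cov(td)
  theo <- observed_base_covariance(cfg)
  # compare on correlations plus marginal variances (scale-free + scale)
  expect_lt(max(abs(cov2cor(emp) - cov2cor(theo))), 0.05)
  rel_var <- abs(diag(emp) - diag(theo)) / diag(theo)
  expect_lt(max(rel_var), 0.12)
})

test_that("oracle error rates follow the Gaussian closed form", {
  cfg <- synthetic_config(seed = 14)
  truth <- generate_cohort(cfg)$truth
  # null separation: FN = 1 - beta, FP = beta
  null_truth <- truth
  null_truth$mahalanobis <- 0
  r0 <- oracle_error_rates(null_truth, 0.05)
  expect_equal(r0$fn_rate, 0.95)
  expect_equal(r0$fp_rate, 0.05)
  # symmetric threshold: FN = pnorm(-Delta) at beta = 0.5
  r5 <- oracle_error_rates(truth, 0.5)
  expect_equal(r5$fn_rate, pnorm(-truth$mahalanobis), tolerance = 1e-12)
  # Monte-Carlo agrees with the closed form on the latent scale
  rmc <- oracle_error_rates(truth, 0.05, method = "monte-carlo",
                            config = cfg, n_mc = 2e5, mc_seed = 2)
  se <- sqrt(r5$fn_rate * (1 - r5$fn_rate) / 2e5)
  rcf <- oracle_error_rates(truth, 0.05)
  expect_lt(abs(rmc$fn_rate - rcf$fn_rate),
            3 * sqrt(rcf$fn_rate * (1 - rcf$fn_rate) / 2e5) + 3 * sqrt(0.05 * 0.95 / 2e5))
  expect_lt(abs(rmc$fp_rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2e5))
})

test_that("a fitted FDA rule attains its Monte-Carlo oracle rate", {
  # large training cohort so the fitted rule is estimated precisely
  cfg <- synthetic_config(n_asd = 1000, n_td = 1000, n_validation = 4000,
                          seed = 15)
  ch <- generate_cohort(cfg)
  spec <- classifier_spec("FDA", subset = c("x4", "x8", "x12", "x21", "x22"))
  fc <- fit_classifier(ch$panel, spec, betas = 0.05)
  val <- generate_validation_cohort(cfg)
  calls <- classify_scores(project(val, fc$model), fc$rules[["0.05"]])
  realized_fn <- mean(calls == "TD")
  # expected FN rate of this very rule under the generative truth
  mc <- oracle_error_rates(ch$truth, 0.05, method = "monte-carlo",
                           config = cfg, model = fc$model, n_mc = 2e5,
                           mc_seed = 3)
  se <- sqrt(mc$fn_rate * (1 - mc$fn_rate) / 4000)
  expect_lt(abs(realized_fn - mc$fn_rate), 3 * se + 0.02)
  # and the Bayes rate lower-bounds what the fitted rule achieves
  bayes <- oracle_error_rates(ch$truth, 0.05)
  expect_gt(realized_fn, bayes$fn_rate - 3 * se - 0.02)
})
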