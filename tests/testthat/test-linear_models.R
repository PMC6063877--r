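test_that("univariate direction follows the higher class", {
  pan <- random_panel(10, 10, 2, seed = 1)
  pan$values[pan$labels == "ASD", 1] <- pan$values[pan$labels == "ASD", 1] + 3
  up <- fit_univariate(pan, "x1")
  expect_equal(unname(up$weights), 1)
  expect_equal(up$intercept, 0)

  down <- pan
  down$values[, 1] <- -down$values[, 1]
  m <- fit_univariate(down, "x1")
  expect_equal(unname(m$weights), -1)

  # equal class means: tie breaks to +1
  tie <- metabolite_panel(cbind(x1 = c(1, 2, 1, 2)),
                          c("ASD", "ASD", "TD", "TD"))
  expect_equal(unname(fit_univariate(tie, "x1")$weights), 1)

  expect_error(fit_univariate(tie, "x9"), "x9")
})

test_that("PCA picks the dominant correlation eigenvector", {
  # two perfectly correlated variables: loading (1,1)/sqrt(2), PC1 carries
  # all the variance
  with_seed(2, x <- rnorm(30))
  pan <- metabolite_panel(cbind(x1 = x, x2 = 2 * x + 1),
                          rep(c("ASD", "TD"), 15))
  m <- fit_pca_direction(pan)
  expect_equal(abs(unname(m$weights)), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(m$extra$variance_explained, 1, tolerance = 1e-9)

  # independently coded power-iteration oracle on a random 5-variable panel
  pan2 <- random_panel(30, 30, 5, seed = 3, effect = 1)
  m2 <- fit_pca_direction(pan2)
  z <- scale(pan2$values)
  cm <- crossprod(z) / (nrow(z) - 1)
  v <- rep(1, 5)
  for (i in 1:2000) v <- {u <- cm %*% v; u / sqrt(sum(u^2))}
  cosang <- abs(sum(v * m2$weights))
  expect_gt(cosang, 1 - 1e-10)  # angle below ~1e-5 rad
})

test_that("PCA ignores labels in fitting but uses them for orientation", {
  pan <- random_panel(20, 20, 4, seed = 4, effect = 2)
  m <- fit_pca_direction(pan)
  relabeled <- pan
  relabeled$labels <- rev(pan$labels)
  m2 <- fit_pca_direction(relabeled)
  # same axis, possibly opposite sign
  expect_equal(abs(sum(m$weights * m2$weights)), 1, tolerance = 1e-9)
  s <- project(pan, m)
  expect_gt(mean(s[pan$labels == "ASD"]), mean(s[pan$labels == "TD"]))
})

test_that("FDA solves the scatter ratio problem", {
  # spherical within-class scatter: direction proportional to the mean gap
  with_seed(5, {
    a <- matrix(rnorm(4000), 2000, 2)
    t <- matrix(rnorm(4000), 2000, 2)
  })
  a[, 1] <- a[, 1] + 3
  vals <- rbind(a, t)
  colnames(vals) <- c("x1", "x2")
  pan <- metabolite_panel(vals, rep(c("ASD", "TD"), each = 2000))
  m <- fit_fda_direction(pan)
  # mean difference is along x1 only
  expect_gt(abs(m$weights["x1"]), 0.99)
  expect_lt(abs(m$weights["x2"]), 0.15)

  # single-variable subset reduces to the univariate direction
  pan2 <- random_panel(15, 15, 3, seed = 6, effect = 1.5)
  f1 <- fit_fda_direction(pan2, "x1")
  u1 <- fit_univariate(pan2, "x1")
  expect_equal(unname(f1$weights), unname(u1$weights), tolerance = 1e-12)
})

test_that("FDA matches the generalized-eigenproblem oracle", {
  for (seed in 1:10) {
    pan <- random_panel(20, 20, 4, seed = 100 + seed, effect = 1)
    m <- fit_fda_direction(pan)
    v <- oracle_fda_direction(pan)
    cosang <- abs(sum(v * m$weights))
    expect_gt(cosang, cos(1e-6))
  }
})

test_that("logistic regression maximizes the penalized likelihood", {
  pan <- random_panel(15, 15, 2, seed = 7, effect = 1)
  m <- fit_logistic(pan)
  expect_true(m$converged)
  z <- scale(pan$values)
  X <- cbind(1, z)
  y <- as.numeric(pan$labels == "ASD")
  pen <- diag(c(0, 1e-4, 1e-4))
  beta_hat <- c(m$intercept, m$weights) * if (m$flipped) -1 else 1
  ll <- function(b) sum(y * (X %*% b) - log1p(exp(X %*% b))) -
    sum(b * (pen %*% b)) / 2
  ll_hat <- ll(beta_hat)
  # numeric gradient at the solution is ~0
  g <- numeric(3)
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- 1e-6
    g[j] <- (ll(beta_hat + e) - ll(beta_hat - e)) / 2e-6
  }
  expect_lt(max(abs(g)), 1e-5)
  # and no random parameter vector beats it
  with_seed(8, draws <- matrix(rnorm(600, sd = 2), 200, 3))
  expect_true(all(apply(draws, 1, ll) <= ll_hat + 1e-9))
})

test_that("logistic regression respects symmetry and null structure", {
  # symmetric classes (x -> -x swaps labels): intercept 0 under ridge
  with_seed(9, x <- matrix(rnorm(80), 40, 2))
  vals <- rbind(x, -x)
  colnames(vals) <- c("x1", "x2")
  pan <- metabolite_panel(vals + 0, rep(c("ASD", "TD"), each = 40))
  m <- fit_logistic(pan)
  expect_lt(abs(m$intercept), 1e-6)

  # identically distributed classes: near-zero weights, C near 1/2
  null_pan <- random_panel(60, 60, 3, seed = 10)
  mn <- fit_logistic(null_pan)
  s <- project(null_pan, mn)
  cs <- c_statistic(fit_score_densities(s, null_pan$labels))
  expect_lt(abs(cs - 0.5), 0.12)
})

test_that("LR on separable data flags non-convergence instead of diverging", {
  pan <- separable_panel(20, 20, seed = 11)
  m <- fit_logistic(pan, ridge = 0)
  expect_false(m$converged)
  expect_true(all(is.finite(m$weights)))
  # with the default ridge the same data converge
  m2 <- fit_logistic(pan)
  expect_true(m2$converged)
})

test_that("lr_membership is a stable sigmoid with complementary classes", {
  expect_equal(lr_membership(0), 0.5)
  expect_lt(lr_membership(1e3), 1e-300)
  s <- c(-20, -1, 0, 2, 50)
  expect_equal(lr_membership(s) + lr_membership(-s), rep(1, 5),
               tolerance = 1e-12)
})

test_that("projection applies training standardization and is affine", {
  pan <- random_panel(12, 12, 3, seed = 12, effect = 1)
  m <- fit_fda_direction(pan)
  s <- project(pan, m)
  expect_gt(mean(s[pan$labels == "ASD"]), mean(s[pan$labels == "TD"]))

  # unit weight on one standardized variable reproduces that column
  u <- fit_univariate(pan, "x2")
  z2 <- (pan$values[, "x2"] - mean(pan$values[, "x2"])) / sd(pan$values[, "x2"])
  expect_equal(unname(project(pan, u)), unname(u$weights * z2),
               tolerance = 1e-12)

  # linearity over samples: score of a row is independent of the others
  one <- project(subset_panel(pan, samples = 3), m)
  expect_equal(unname(one), unname(s[3]), tolerance = 1e-12)
  expect_error(project(subset_panel(pan, variables = c("x1", "x2")), m),
               "missing")
})

test_that("all four fitters are permutation-equivariant", {
  pan <- random_panel(15, 15, 4, seed = 13, effect = 1)
  perm_s <- with_seed(14, sample(n_samples(pan)))
  perm_v <- c("x3", "x1", "x4", "x2")
  shuffled <- subset_panel(pan, samples = perm_s, variables = perm_v)
  for (fitter in list(
    function(p) fit_pca_direction(p, sort(panel_variables(p))),
    function(p) fit_fda_direction(p, sort(panel_variables(p))),
    function(p) fit_logistic(p, sort(panel_variables(p))),
    function(p) fit_univariate(p, "x2")
  )) {
    m1 <- fitter(pan)
    m2 <- fitter(shuffled)
    expect_equal(m1$weights[m1$subset], m2$weights[m1$subset],
                 tolerance = 1e-8)
  }
})

test_that("FDA fitted C-statistic dominates the best single variable", {
  pan <- random_panel(25, 25, 4, seed = 15, effect = 1)
  fda_c <- c_statistic(fit_score_densities(
    project(pan, fit_fda_direction(pan)), pan$labels))
  uni_c <- max(vapply(panel_variables(pan), function(v) {
    c_statistic(fit_score_densities(project(pan, fit_univariate(pan, v)),
                                    pan$labels))
  }, numeric(1)))
  expect_gte(fda_c, uni_c - 0.02)  # KDE smoothing allows small slack
})

test_that("models survive a text round trip", {
  pan <- random_panel(10, 10, 3, seed = 16, effect = 1)
  m <- fit_logistic(pan)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(project(pan, back), project(pan, m), tolerance = 1e-12)
})
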