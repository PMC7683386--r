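test_that("biomarker ratio filter matches the hand oracle", {
  # identical ratios: SD = 0, nobody removed
  co <- toy_cohort(5)
  co$ttau <- co$abeta * 0.5
  expect_equal(nrow(ratio_outlier_filter(co, 6)), nrow(co))

  # lone extreme outlier among n = 50: hand-computed z exceeds 6
  co <- data.frame(id = sprintf("R%02d", 1:50), abeta = rep(100, 50),
                   ttau = c(rep(100, 49), 5000))
  ratios <- co$ttau / co$abeta
  z <- abs(ratios - mean(ratios)) / sd(ratios)   # independent arithmetic
  expect_gt(z[50], 6)
  expect_true(all(z[-50] < 6))
  kept <- ratio_outlier_filter(co, 6)
  expect_equal(nrow(kept), 49)
  expect_equal(attr(kept, "excluded"), "R50")

  # the same construction at n = 20 cannot exceed 6 SD: a lone outlier is
  # at most (n-1)/sqrt(n) sample SDs from the mean
  co20 <- co[c(1:19, 50), ]
  expect_lt(max(abs(scale(co20$ttau / co20$abeta))), 6)
  expect_equal(nrow(ratio_outlier_filter(co20, 6)), 20)

  # k = Inf is the identity
  expect_equal(nrow(ratio_outlier_filter(co, Inf)), 50)
})

test_that("missing biomarkers are flagged, not dropped", {
  co <- toy_cohort(5)
  co$abeta[2] <- NA
  kept <- ratio_outlier_filter(co, 6)
  expect_equal(nrow(kept), nrow(co))
  expect_true(kept$biomarkers_missing[2])
  expect_false(any(kept$biomarkers_missing[-2]))
  co$abeta <- NA
  expect_error(ratio_outlier_filter(co, 6), "complete")
})

test_that("design construction codes factors and centers covariates", {
  co <- simulate_cohort(4, seed = 1)
  # intercept only
  d0 <- build_design(co, character(0))
  expect_equal(dim(d0$X), c(20, 1))
  expect_true(all(d0$X == 1))

  # 5-level diagnosis + age: 1 + 4 + 1 columns
  d1 <- build_design(co, c("diagnosis", "age"))
  expect_equal(ncol(d1$X), 6)
  expect_equal(colnames(d1$X)[2:5],
               paste0("diagnosis", c("SMC", "EMCI", "LMCI", "AD")))
  expect_equal(sum(d1$X[, "diagnosisAD"]), 4)
  expect_equal(mean(d1$X[, "age"]), 0, tolerance = 1e-12)

  # sex as a single male indicator
  d2 <- build_design(co, "sex")
  expect_equal(colnames(d2$X)[2], "sexM")
  expect_equal(d2$X[, "sexM"], as.numeric(co$sex == "M"))
})

test_that("interaction columns are products of centered terms", {
  co <- toy_cohort(3)  # 6 subjects, HC and AD
  d <- build_design(co, c("diagnosis", "abeta", "diagnosis:abeta"))
  expect_equal(colnames(d$X),
               c("(intercept)", "diagnosisAD", "abeta",
                 "diagnosisAD:abeta"))
  # entry-wise hand computation
  expect_equal(d$X[, "diagnosisAD:abeta"],
               as.numeric(co$diagnosis == "AD") *
                 (co$abeta - mean(co$abeta)))
})

test_that("rank-deficient designs are rejected with the offending column", {
  co <- toy_cohort(3)
  co$age2 <- co$age
  expect_error(build_design(co, c("age", "age2")), "age2")
})

test_that("voxelwise OLS satisfies the normal equations", {
  set.seed(21)
  n <- 12
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(intercept)", "a", "b")
  beta_true <- matrix(rnorm(15), 5, 3)
  Y <- beta_true %*% t(X)  # noiseless
  fit <- fit_glm(Y, X)
  expect_equal(fit$coef, beta_true, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$sigma2, rep(0, 5), tolerance = 1e-16)

  # tiny exact case: y = t
  fit2 <- fit_glm(c(1, 2, 3), cbind(1, 1:3))
  expect_equal(as.vector(fit2$coef), c(0, 1), tolerance = 1e-12)

  # random response vs an independent lm() oracle
  Y <- Y + matrix(rnorm(5 * n), 5, n)
  fit <- fit_glm(Y, X)
  for (v in 1:5) {
    or <- lm(Y[v, ] ~ X[, 2] + X[, 3])
    expect_equal(as.vector(fit$coef[v, ]), as.vector(coef(or)),
                 tolerance = 1e-8)
    expect_equal(fit$sigma2[v], summary(or)$sigma^2, tolerance = 1e-8)
  }
})

test_that("contrast t equals the pooled two-sample t", {
  set.seed(22)
  g <- rep(c(0, 1), each = 4)
  y <- c(rnorm(4, 1, 0.5), rnorm(4, 2, 0.5))
  X <- cbind(1, g)
  fit <- fit_glm(y, X)
  sm <- contrast_t(fit, c(0, 1))
  or <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  expect_equal(as.vector(sm$stat), as.vector(or$statistic),
               tolerance = 1e-10)
  expect_equal(as.vector(sm$p), or$p.value, tolerance = 1e-10)

  # zero contrast: t = 0, p = 1; identical groups: t = 0
  expect_equal(as.vector(contrast_t(fit, c(0, 0))$stat), 0)
  expect_equal(as.vector(contrast_t(fit, c(0, 0))$p), 1)
  y2 <- rep(c(1, 2, 3, 4), 2)
  expect_equal(as.vector(contrast_t(fit_glm(y2, X), c(0, 1))$stat), 0)
})

test_that("omnibus F equals the one-way ANOVA oracle", {
  set.seed(23)
  grp <- factor(rep(c("a", "b", "c"), each = 5))
  y <- rnorm(15) + rep(c(0, 0.5, 2), each = 5)
  X <- cbind(1, as.numeric(grp == "b"), as.numeric(grp == "c"))
  colnames(X) <- c("(intercept)", "gb", "gc")
  fit <- fit_glm(y, X)
  fm <- omnibus_f(fit, 2:3)
  or <- summary(aov(y ~ grp))[[1]]
  expect_equal(as.vector(fm$stat), or[["F value"]][1], tolerance = 1e-8)
  expect_equal(as.vector(fm$p), or[["Pr(>F)"]][1], tolerance = 1e-8)

  # equal group means: F near 0 for exactly balanced values
  yb <- rep(c(1, 2, 3, 4, 5), 3)
  expect_lt(as.vector(omnibus_f(fit_glm(yb, X), 2:3)$stat), 1e-12)

  # noiseless response with null term columns: flagged undefined
  y0 <- rep(1, 15) + 0.3 * rnorm(15) * 0  # constant
  expect_true(is.na(as.vector(omnibus_f(fit_glm(y0, X), 2:3)$stat)))
})

test_that("omnibus F is invariant to the reference-group coding", {
  set.seed(24)
  grp <- rep(c("a", "b", "c"), each = 6)
  y <- matrix(rnorm(3 * 18), 3, 18)
  Xa <- cbind(1, as.numeric(grp == "b"), as.numeric(grp == "c"))
  Xb <- cbind(1, as.numeric(grp == "a"), as.numeric(grp == "c"))
  fa <- omnibus_f(fit_glm(y, Xa), 2:3)
  fb <- omnibus_f(fit_glm(y, Xb), 2:3)
  expect_equal(fa$stat, fb$stat, tolerance = 1e-10)
})

test_that("null voxelwise p-values are uniform", {
  set.seed(25)
  nvox <- 20000; n <- 20
  X <- cbind(1, rnorm(n), rep(0:1, n / 2))
  Y <- matrix(rnorm(nvox * n), nvox, n)
  sm <- contrast_t(fit_glm(Y, X), c(0, 1, 0))
  frac <- mean(sm$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nvox) + 0.002)
})

test_that("permutation FWE threshold is deterministic and ordered in alpha", {
  set.seed(26)
  n <- 24
  X <- cbind(1, rep(0:1, each = n / 2), rnorm(n))
  Y <- matrix(rnorm(300 * n), 300, n)
  t1 <- permutation_fwe_threshold(Y, X, 2, n_perm = 200, alpha = 0.05,
                                  seed = 99)
  t2 <- permutation_fwe_threshold(Y, X, 2, n_perm = 200, alpha = 0.05,
                                  seed = 99)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t_loose <- permutation_fwe_threshold(Y, X, 2, n_perm = 200,
                                       alpha = 0.25, seed = 99)
  t_tight <- permutation_fwe_threshold(Y, X, 2, n_perm = 200,
                                       alpha = 0.01, seed = 99)
  expect_lte(as.numeric(t_loose), as.numeric(t1))
  expect_lte(as.numeric(t1), as.numeric(t_tight))
  # alpha = 1: the minimum of the max-statistic distribution
  t_all <- permutation_fwe_threshold(Y, X, 2, n_perm = 200, alpha = 1,
                                     seed = 99)
  expect_equal(as.numeric(t_all), min(attr(t_all, "max_stats")))
  expect_error(permutation_fwe_threshold(Y, X, 2, n_perm = 150,
                                         alpha = 0.001, seed = 1),
               "too few")
})

test_that("permutation FWE control is near nominal under the null", {
  set.seed(27)
  n <- 16
  X <- cbind(1, rep(0:1, each = n / 2), rnorm(n))
  hits <- replicate(60, {
    Y <- matrix(rnorm(150 * n), 150, n)
    fit <- fit_glm(Y, X)
    fobs <- omnibus_f(fit, 2)
    thr <- permutation_fwe_threshold(Y, X, 2, n_perm = 200,
                                     alpha = 0.05)
    any(fobs$stat > as.numeric(thr), na.rm = TRUE)
  })
  # 60 null datasets at alpha 0.05: expect a handful of hits at most
  expect_lte(mean(hits), 0.18)
})
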