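zero_trace <- function(n) matrix(0, n, 6)

test_that("framewise displacement follows the backward-difference formula", {
  expect_equal(framewise_displacement(zero_trace(10)), rep(0, 10))

  tr <- zero_trace(10)
  tr[5:10, 1] <- 0.1  # single 0.1 mm step in x at frame 5
  fd <- framewise_displacement(tr)
  expect_equal(fd[5], 0.1)
  expect_equal(fd[-5], rep(0, 9))

  tr <- zero_trace(8)
  tr[3:8, 5] <- 0.02  # 0.02 rad pitch step: 50 mm * 0.02 = 1 mm
  expect_equal(framewise_displacement(tr)[3], 1.0)
  expect_equal(framewise_displacement(tr, sphere_radius = 100)[3], 2.0)

  # hand-computed mixed frame
  tr <- zero_trace(3)
  tr[2, ] <- c(0.1, -0.2, 0.05, 0.001, -0.002, 0.003)
  expect_equal(framewise_displacement(tr)[2],
               0.1 + 0.2 + 0.05 + 50 * (0.001 + 0.002 + 0.003))
})

test_that("FD is non-negative and offset-invariant", {
  set.seed(2)
  tr <- matrix(rnorm(60 * 6, sd = 0.1), 60, 6)
  fd <- framewise_displacement(tr)
  expect_true(all(fd >= 0))
  expect_equal(framewise_displacement(sweep(tr, 2, rnorm(6), "+")), fd)
})

test_that("QC applies the 2 mm / 2 degree / 0.5 mm mean-FD rules", {
  expect_true(qc_subject(zero_trace(20))$pass)

  tr <- zero_trace(20); tr[10, 2] <- 2.5
  r <- qc_subject(tr)
  expect_false(r$pass)
  expect_equal(r$reasons, "translation")

  tr <- zero_trace(20); tr[10, 4] <- 2.5 * pi / 180
  expect_equal(qc_subject(tr)$reasons, "rotation")

  # jittery 0.2 mm steps alternate: FD about 0.6 per frame
  tr <- zero_trace(21); tr[seq(2, 20, 2), 1:3] <- 0.2
  r <- qc_subject(tr)
  expect_false(r$pass)
  expect_true("mean_fd" %in% r$reasons)
  expect_lt(r$max_translation, 2)

  # exactly at a limit is allowed ("no more than")
  tr <- zero_trace(20); tr[10, 1] <- 2
  expect_true(qc_subject(tr)$pass)
})

test_that("loosening any QC threshold never flips pass to fail", {
  set.seed(5)
  flips <- logical(0)
  passes <- 0
  for (i in 1:30) {
    s <- runif(1, 0.005, 0.6)
    tr <- cbind(matrix(rnorm(40 * 3, sd = s), 40, 3),
                matrix(rnorm(40 * 3, sd = s / 100), 40, 3))
    base <- qc_subject(tr)
    loose <- qc_subject(tr, max_trans = 4, max_rot = 4, max_mean_fd = 1)
    flips <- c(flips, base$pass && !loose$pass)
    passes <- passes + base$pass
  }
  expect_false(any(flips))
  expect_gt(passes, 0)  # the sample actually exercises the passing branch
})

test_that("initial-volume discard trims image and trace together", {
  img <- array(seq_len(2 * 2 * 2 * 10), c(2, 2, 2, 10))
  tr <- matrix(rnorm(60), 10, 6)
  out <- discard_initial_volumes(img, tr, k = 2)
  expect_equal(dim(out$image)[4], 8)
  expect_equal(nrow(out$trace), 8)
  expect_equal(out$image[, , , 1], img[, , , 3])
  expect_equal(out$trace[1, ], tr[3, ])
  expect_identical(discard_initial_volumes(img, tr, k = 0)$image, img)
  expect_error(discard_initial_volumes(img, tr, k = 10), "smaller")
})

test_that("nuisance regression removes the regressors and restores the mean", {
  set.seed(9)
  T_ <- 80
  # regressing a series on itself gives the constant mean
  x <- rnorm(T_, mean = 3)
  out <- nuisance_regress(x, x)
  expect_equal(out, rep(mean(x), T_), tolerance = 1e-10)

  # regressor orthogonal to the demeaned series leaves it unchanged
  x <- rnorm(T_)
  z <- rnorm(T_)
  z <- z - mean(z)
  z_orth <- z - sum(z * (x - mean(x))) / sum((x - mean(x))^2) *
    (x - mean(x))
  expect_equal(nuisance_regress(x, z_orth), x, tolerance = 1e-10)

  # known signal removal: residual variance close to the noise variance
  g <- rnorm(T_)
  noise <- rnorm(T_, sd = 0.5)
  y <- 2 * g + noise
  res <- nuisance_regress(y, g)
  expect_lt(var(res), var(y) / 4)
  expect_equal(var(res), var(noise), tolerance = 0.25)

  # residuals orthogonal to every regressor
  Z <- matrix(rnorm(T_ * 4), T_, 4)
  res <- nuisance_regress(y, Z)
  rel <- abs(crossprod(Z, res - mean(res))) /
    (sqrt(colSums(Z^2)) * sqrt(sum((res - mean(res))^2)))
  expect_true(all(rel < 1e-8))
})

test_that("nuisance regression is idempotent and flags collinearity", {
  set.seed(10)
  y <- rnorm(50)
  Z <- matrix(rnorm(100), 50, 2)
  once <- nuisance_regress(y, Z)
  expect_equal(nuisance_regress(once, Z), once, tolerance = 1e-10)
  Zbad <- cbind(Z, Z[, 1] * 2)
  colnames(Zbad) <- c("a", "b", "c")
  expect_error(nuisance_regress(y, Zbad), "collinear")
})

test_that("gaussian smoothing has the definitional kernel behavior", {
  v <- array(rnorm(10^3), c(10, 10, 10))
  expect_identical(gaussian_smooth(v, 0, c(2, 2, 2)), v)
  expect_error(gaussian_smooth(v, -1, c(2, 2, 2)), "non-negative")

  # unit impulse, fwhm = 2.3548 voxels -> sigma = 1 voxel:
  # profile along an axis proportional to exp(-k^2/2)
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  sm <- gaussian_smooth(imp, 2 * sqrt(2 * log(2)), c(1, 1, 1))
  prof <- sm[8:12, 8, 8] / sm[8, 8, 8]
  expect_equal(prof, exp(-(0:4)^2 / 2), tolerance = 1e-6)

  # constant volume unchanged (unit-mass kernel, reflective boundary)
  cv <- array(4.2, c(8, 8, 8))
  expect_equal(gaussian_smooth(cv, 6, c(3, 3, 3)),
               cv, tolerance = 1e-12, ignore_attr = TRUE)

  # mean preserved, spatial variance strictly reduced
  set.seed(12)
  v <- array(rnorm(12^3), c(12, 12, 12))
  sv <- gaussian_smooth(v, 5, c(3, 3, 3))
  expect_equal(mean(sv), mean(v), tolerance = 1e-6)
  expect_lt(var(as.vector(sv)), var(as.vector(v)))
})

test_that("smoothing applies volume-wise to 4D images", {
  set.seed(13)
  img <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  sm <- gaussian_smooth(img, 4, c(3, 3, 3))
  expect_equal(sm[, , , 2],
               gaussian_smooth(img[, , , 2], 4, c(3, 3, 3)),
               ignore_attr = TRUE)
})
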