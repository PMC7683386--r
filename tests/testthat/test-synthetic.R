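test_that("AR(1) generator is stationary and reproducible", {
  x1 <- ar1_series(200, 0.5, seed = 4)
  x2 <- ar1_series(200, 0.5, seed = 4)
  expect_identical(x1, x2)
  expect_error(ar1_series(100, 1.0), "phi")
  expect_error(ar1_series(100, 0.5, sigma = 0), "sigma")
  # stationary variance sigma^2 / (1 - phi^2)
  set.seed(44)
  long <- ar1_series(1e5, 0.6, sigma = 2)
  expect_equal(var(long), 4 / (1 - 0.36), tolerance = 0.05)
  # lag-one autocorrelation near phi
  expect_equal(cor(long[-1], long[-1e5]), 0.6, tolerance = 0.02)
})

test_that("cohort simulation is balanced, typed and reproducible", {
  co <- simulate_cohort(5, seed = 8)
  expect_equal(nrow(co), 25)
  expect_equal(unname(table(co$diagnosis)), rep(5L, 5),
               ignore_attr = TRUE)
  expect_identical(co, simulate_cohort(5, seed = 8))
  expect_true(all(co$age > 0))
  expect_true(all(co$sex %in% c("M", "F")))
  expect_true(all(co$mmse >= 0 & co$mmse <= 30))
  expect_true(all(co$abeta > 0 & co$ttau > 0))
  expect_error(simulate_cohort(1), "n_per_group")
})

test_that("configured cognitive decline shows in large-sample group means", {
  co <- simulate_cohort(150, seed = 9)
  mm <- tapply(co$mmse, co$diagnosis, mean)
  # AD clearly lowest; cognitively normal groups above the MCI/AD groups
  expect_true(all(mm["AD"] < mm[c("HC", "SMC", "EMCI", "LMCI")]))
  expect_true(all(mm[c("HC", "SMC")] > mm[c("LMCI", "AD")] ))
  # CSF A-beta declines and t-tau rises along the continuum
  ab <- tapply(co$abeta, co$diagnosis, mean)
  tt <- tapply(co$ttau, co$diagnosis, mean)
  expect_true(all(diff(ab) < 0))
  expect_true(all(diff(tt) > 0))
})

test_that("ROI blocks are disjoint, labeled and inside the brain mask", {
  g <- sim_geometry(c(24, 24, 24), n_timepoints = 30)
  rois <- make_roi_masks(g)
  expect_equal(sort(unique(as.vector(rois$labels))), 0:4)
  for (l in 1:4)
    expect_true(all(rois$brain_mask[rois$labels == l]))
  # rectangular blocks of equal configured size
  sizes <- tabulate(rois$labels[rois$labels > 0])
  expect_equal(length(unique(sizes)), 1)
  expect_equal(sizes[1], 6^3)
  expect_error(sim_geometry(c(8, 8, 8)), "16")
})

test_that("subject phi encodes the implanted effect directions", {
  eff <- effect_spec()
  base <- data.frame(diagnosis = "HC", age = 73, education = 16,
                     abeta = 180)
  older <- base; older$age <- 83
  educated <- base; educated$education <- 20
  amyloid <- base; amyloid$abeta <- 120  # more pathology
  # controls: entropy rises with age and pathology -> phi falls
  expect_lt(subject_phi(older, eff), subject_phi(base, eff))
  expect_lt(subject_phi(amyloid, eff), subject_phi(base, eff))
  # education suppresses entropy in controls -> phi rises
  expect_gt(subject_phi(educated, eff), subject_phi(base, eff))
  # patients: directions flip for age and pathology, education inert
  pat <- base; pat$diagnosis <- "LMCI"
  pat_old <- pat; pat_old$age <- 83
  pat_amy <- pat; pat_amy$abeta <- 120
  pat_edu <- pat; pat_edu$education <- 20
  expect_gt(subject_phi(pat_old, eff), subject_phi(pat, eff))
  expect_gt(subject_phi(pat_amy, eff), subject_phi(pat, eff))
  expect_equal(subject_phi(pat_edu, eff), subject_phi(pat, eff))
  # stage profile of phi is U-shaped: lowest at EMCI, highest at AD
  phis <- sapply(c("HC", "SMC", "EMCI", "LMCI", "AD"), function(d) {
    b <- base; b$diagnosis <- d; subject_phi(b, eff)
  })
  expect_equal(names(which.min(phis)), "EMCI")
  expect_equal(names(which.max(phis)), "AD")
  # clipping
  ext <- base; ext$age <- 200
  expect_gte(subject_phi(ext, eff), eff$phi_range[1])
  expect_lte(subject_phi(ext, eff), eff$phi_range[2])
})

test_that("motion severity 'fail' violates a QC rule and 'low' passes", {
  set.seed(61)
  for (i in 1:5) {
    expect_true(qc_subject(simulate_motion(140, "low"))$pass)
    expect_false(qc_subject(simulate_motion(140, "fail"))$pass)
  }
  m1 <- simulate_motion(100, "fail", seed = 3)
  expect_identical(m1, simulate_motion(100, "fail", seed = 3))
})

test_that("subject image generation is deterministic and phi-structured", {
  g <- sim_geometry(c(16, 16, 16), n_timepoints = 40)
  co <- simulate_cohort(2, seed = 5)
  rec <- co[co$diagnosis == "AD", ][1, ]
  s1 <- simulate_subject_image(rec, g, rois = make_roi_masks(g), seed = 6)
  s2 <- simulate_subject_image(rec, g, rois = make_roi_masks(g), seed = 6)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$motion, s2$motion)
  expect_equal(dim(s1$image), c(16, 16, 16, 40))
  rois <- make_roi_masks(g)
  expect_equal(unique(as.vector(s1$phi[rois$labels %in% 1:3])),
               subject_phi(rec, effect_spec()))
  expect_equal(unique(as.vector(s1$phi[rois$labels == 4])),
               effect_spec()$phi_null)
  # forced motion class override
  sf <- simulate_subject_image(rec, g, rois = rois, motion_class = "fail",
                               seed = 7)
  expect_false(qc_subject(sf$motion)$pass)
})

test_that("a null effect specification yields a spatially flat entropy map", {
  eff0 <- effect_spec(phi_stage = c(HC = 0.5, SMC = 0.5, EMCI = 0.5,
                                    LMCI = 0.5, AD = 0.5),
                      phi_null = 0.5,
                      age_slope = c(control = 0, patient = 0),
                      education_slope = c(control = 0, patient = 0),
                      abeta_slope = c(control = 0, patient = 0),
                      motion_fail_rate = 0)
  g <- sim_geometry(c(16, 16, 16), n_timepoints = 80)
  rois <- make_roi_masks(g)
  co <- simulate_cohort(3, seed = 10)
  diffs <- sapply(seq_len(10), function(i) {
    s <- simulate_subject_image(co[i, ], g, eff0, rois = rois,
                                seed = 100 + i)
    bv <- ben_map(s$image, rois$brain_mask, m = 3, r = 0.6)
    mean(bv$values[rois$labels %in% 1:3 & bv$mask]) -
      mean(bv$values[rois$labels == 4 & bv$mask])
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se + 0.005)
})
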