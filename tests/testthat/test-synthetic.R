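test_that("same seed gives bit-identical phantoms and cohorts", {
  s <- thin_phantom_spec(seed = 81)
  p1 <- make_phantom(s); p2 <- make_phantom(s)
  expect_identical(p1$volume$voxels, p2$volume$voxels)
  expect_identical(p1$truth$at_volume_L, p2$truth$at_volume_L)
  expect_identical(make_cohort(cohort_spec(seed = 81)),
                   make_cohort(cohort_spec(seed = 81)))
  p3 <- make_phantom(thin_phantom_spec(seed = 82))
  expect_false(identical(p1$volume$voxels, p3$volume$voxels))
})

test_that("ground-truth volumes equal voxel counts of the truth masks", {
  ph <- make_phantom(thin_phantom_spec(seed = 83))
  vox_l <- voxel_volume_liters(ph$volume)
  expect_identical(ph$truth$at_volume_L, sum(ph$truth$at_mask) * vox_l)
  expect_identical(ph$truth$lt_volume_L, sum(ph$truth$lt_mask) * vox_l)
  expect_false(any(ph$truth$at_mask & ph$truth$lt_mask))
})

test_that("shell ground truth matches the analytic cylinder annulus", {
  ph <- make_phantom(thin_phantom_spec(seed = 84))
  g <- ctcomp:::phantom_geometry(ph$spec)
  nz_torso <- g$torso_z[2] - g$torso_z[1] + 1
  # count AT voxels in the torso section outside the visceral blobs
  tor <- ph$truth$at_mask[g$torso_z[1]:g$torso_z[2], , ]
  shell_analytic <- pi * (g$torso$at^2 - g$torso$muscle^2) * nz_torso
  blob_analytic <- pi * sum(vapply(g$blobs, function(b) b$r^2, 0)) * nz_torso
  # within one voxel layer of the interfaces
  layer <- 2 * pi * (g$torso$at + g$torso$muscle) * nz_torso
  expect_lt(abs(sum(tor) - (shell_analytic + blob_analytic)),
            layer)
  expect_lt(abs(sum(tor) - (shell_analytic + blob_analytic)) /
            (shell_analytic + blob_analytic), 0.02)
})

test_that("separable zero-noise phantom classifies exactly at the midpoint", {
  sp <- thin_phantom_spec(at = c(-90, 0), muscle = c(55, 0),
                          bone = c(400, 0), skin = c(55, 0),
                          noise_sd = 0, seed = 85)
  ph <- make_phantom(sp)
  m <- classify(ph$volume, round((-90 + 55) / 2))
  # partial-volume ramp voxels are the only allowed disagreements
  at_vs_truth <- sum(xor(m$at_mask, ph$truth$at_mask))
  expect_lt(at_vs_truth / sum(ph$truth$at_mask), 0.06)
  # away from interfaces the match is exact: erode by ignoring ramp HU
  core <- ph$volume$voxels == -90
  expect_true(all(m$at_mask[core]))
  expect_false(any(m$lt_mask[core]))
})

test_that("canonical lines land in the correct tissue by construction", {
  sp <- thin_phantom_spec(at = c(-90, 0), muscle = c(55, 0),
                          bone = c(400, 0), skin = c(20, 0),
                          noise_sd = 0, seed = 86)
  ph <- make_phantom(sp)
  lm <- ph$landmarks
  slice_for <- function(level) switch(level,
    l4l5 = lm$l4l5, femur85 = femoral_fraction_slice(lm, 0.85),
    femur15 = femoral_fraction_slice(lm, 0.15))
  for (i in seq_len(nrow(ph$lines))) {
    ln <- ph$lines[i, ]
    sl <- ph$volume$voxels[slice_for(ln$slice_level), , ]
    prof <- sample_line_profile(sl, c(ln$p0_row, ln$p0_col),
                                c(ln$p1_row, ln$p1_col), label = ln$label)
    if (ln$label %in% c("a", "b", "e", "g")) {
      expect_true(all(prof$values == -90),
                  label = paste("line", ln$label, "pure"))
    } else {
      frac_at <- mean(prof$values < -17)
      expect_gt(frac_at, 0.25)
      expect_lt(frac_at, 0.75)
    }
  }
})

test_that("bias shifts the calibrated cutoff (translation equivariance)", {
  base <- thin_phantom_spec(seed = 87)
  cut_at <- function(bias) {
    sp <- base; sp$bias_hu <- bias
    ph <- make_phantom(sp)
    den <- median_denoise(ph$volume)
    suppressWarnings(calibrate_volume(den, ph$lines, ph$landmarks))$cutoff
  }
  c0 <- cut_at(0)
  expect_lte(abs(cut_at(15) - (c0 + 15)), 1)
  expect_lte(abs(cut_at(-15) - (c0 - 15)), 1)
})

test_that("cohort generator satisfies its construction invariants", {
  co <- make_cohort(cohort_spec(seed = 88))
  expect_identical(nrow(co), 41L)
  expect_identical(sum(co$sex == "F"), 5L)
  expect_silent(validate_cohort(co))
  expect_true(all(co[, grep("area", names(co))] > 0))
  # residual-free cohort: OLS recovers the printed equation exactly
  co0 <- make_cohort(cohort_spec(seed = 89,
                                 abs_pe = c(at_l3l4 = 0, at_l4l5 = 0,
                                            at_midthigh = 0, lt_l3l4 = 0,
                                            lt_l4l5 = 0, lt_midthigh = 0)))
  f <- suppressWarnings(fit_ols(co0$at_area_l4l5, co0$at_volume_L))
  expect_equal(f$slope, 0.074, tolerance = 1e-9)
  expect_equal(f$intercept, 2.737, tolerance = 1e-7)
  f2 <- suppressWarnings(fit_ols(co0$lt_area_midthigh, co0$lt_volume_L))
  expect_equal(f2$slope, 0.108, tolerance = 1e-9)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(at = c(-90, 60)), "separable")
  expect_error(phantom_spec(noise_sd = -1), "non-negative")
  expect_error(cohort_spec(n = 2), "n >= 3")
  expect_error(make_phantom(phantom_spec(shape = c(16, 16, 16))),
               "impossible")
})
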