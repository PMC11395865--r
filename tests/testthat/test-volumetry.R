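test_that("a constructed sphere is segmented exactly", {
  dims <- c(20, 20, 20)
  sph <- sphere_mask(dims, c(10, 10, 10), 4.9)   # about 500 voxels
  x <- array(0, dims); x[sph] <- 10
  d <- make_difference(x)
  cm <- segment_compartments(d, threshold = 5, min_component_mm3 = 10)
  expect_identical(cm$washout_mask, sph)
  expect_false(any(cm$washin_mask))
  # negation swaps the compartments exactly
  cm2 <- segment_compartments(make_difference(-x), threshold = 5,
                              min_component_mm3 = 10)
  expect_identical(cm2$washin_mask, sph)
  expect_false(any(cm2$washout_mask))
})

test_that("small components fall to the minimum-size filter", {
  x <- array(0, c(12, 12, 12))
  x[2:6, 2:6, 2:6] <- 10      # 125 voxels, kept
  x[10, 10, 10] <- 10         # isolated voxel, dropped at 10 mm3
  cm <- segment_compartments(make_difference(x), threshold = 5,
                             min_component_mm3 = 10)
  expect_equal(sum(cm$washout_mask), 125)
})

test_that("threshold monotonicity: higher thresholds never grow compartments", {
  set.seed(51)
  x <- array(rnorm(16^3, sd = 4), c(16, 16, 16))
  d <- make_difference(x)
  vols <- vapply(c(2, 4, 6, 8), function(th) {
    cm <- segment_compartments(d, threshold = th, min_component_mm3 = 0)
    c(sum(cm$washout_mask), sum(cm$washin_mask))
  }, c(0, 0))
  expect_true(all(diff(vols[1, ]) <= 0))
  expect_true(all(diff(vols[2, ]) <= 0))
})

test_that("an empty roi is rejected", {
  d <- make_difference(array(1, c(4, 4, 4)) + 0)
  expect_error(segment_compartments(d, threshold = 0.5,
                                    roi = array(FALSE, c(4, 4, 4))),
               "empty roi")
})

test_that("measurement implements the wash-out ratio formula exactly", {
  dims <- c(24, 24, 12)
  wo <- array(FALSE, dims); wo[1:10, 1:5, 1:5] <- TRUE   # 250 voxels
  wi <- array(FALSE, dims); wi[11:20, 6:20, 6:10] <- TRUE  # 750 voxels
  cm <- structure(list(washout_mask = wo, washin_mask = wi, threshold = 1,
                       min_component_mm3 = 0, spacing = c(1, 1, 1),
                       roi = NULL, geometry = NULL),
                  class = "washout_compartments")
  vr <- measure_compartments(cm)
  expect_equal(vr$washout_mm3, 250)
  expect_equal(vr$washin_mm3, 750)
  expect_equal(vr$washout_ratio, 0.25)
  # boundary cases: empty wash-in gives 1, both empty is flagged undefined
  cm$washin_mask <- array(FALSE, dims)
  expect_equal(measure_compartments(cm)$washout_ratio, 1)
  cm$washout_mask <- array(FALSE, dims)
  vr0 <- measure_compartments(cm)
  expect_false(vr0$ratio_defined)
  expect_true(is.na(vr0$washout_ratio))
  expect_equal(vr0$washout_mm3, 0)
})

test_that("volumes scale exactly with the voxel volume", {
  dims <- c(10, 10, 10)
  wo <- array(FALSE, dims); wo[1:10, 1:5, 1:2] <- TRUE   # 100 voxels
  cm <- structure(list(washout_mask = wo, washin_mask = array(FALSE, dims),
                       threshold = 1, min_component_mm3 = 0,
                       spacing = c(1, 1, 2), roi = NULL, geometry = NULL),
                  class = "washout_compartments")
  expect_equal(measure_compartments(cm)$washout_mm3, 200)
  for (s in c(0.5, 2, 3)) {
    got <- measure_compartments(cm, spacing = c(1, 1, 2) * s)$washout_mm3
    expect_identical(got, 200 * s^3)
  }
})

test_that("phantom compartments are recovered with high Dice at SNR 20", {
  ph <- generate_phantom(seed = 16, snr = 20,
                         layout = default_layout(tumor_volume_cm3 = 2))
  nm <- normalize_means(correct_bias(ph$early)$corrected,
                        correct_bias(ph$late)$corrected)
  fg <- foreground_mask(nm$early)
  d <- subtract_series(nm$early, nm$late, mask = fg)
  cm <- segment_compartments(d)
  expect_gte(dice_coef(cm$washout_mask, ph$truth$washout_mask), 0.85)
  expect_gte(dice_coef(cm$washin_mask, ph$truth$washin_mask), 0.85)
})

test_that("rCBV volumetry reproduces the constructed slab cases", {
  # everything at rCBV 1.0 stays below the 1.2 threshold
  flat <- volume(array(1, c(20, 20, 10)) + 0)
  p0 <- segment_perfusion(flat)
  expect_equal(p0$volume_mm3, 0)
  expect_true(is.na(p0$max_rcbv))
  # a 10 x 10 x 6 slab at 2.0: cross-section 1 cm^2, volume 600 mm^3
  r <- array(1, c(30, 30, 12)) + 0
  r[6:15, 6:15, 4:9] <- 2
  p1 <- segment_perfusion(volume(r))
  expect_equal(p1$volume_mm3, 600)
  expect_equal(p1$max_rcbv, 2)
  # cross-section 0.1 cm^2 (2 x 5 mm) falls to the 0.25 cm^2 filter
  r2 <- array(1, c(30, 30, 12)) + 0
  r2[6:7, 6:10, 4:9] <- 2
  expect_equal(segment_perfusion(volume(r2))$volume_mm3, 0)
  # the filter is in-plane: a thin but wide slab passes
  r3 <- array(1, c(30, 30, 12)) + 0
  r3[6:15, 6:15, 4] <- 2
  expect_equal(segment_perfusion(volume(r3))$volume_mm3, 100)
})

test_that("an enhancement mask restricts the perfusion compartment", {
  r <- array(1, c(20, 20, 10)) + 0
  r[3:12, 3:12, 3:8] <- 2
  enh <- array(FALSE, c(20, 20, 10)); enh[3:12, 3:7, 3:8] <- TRUE
  p <- segment_perfusion(volume(r), enhancement_mask = enh)
  expect_equal(p$volume_mm3, 10 * 5 * 6)
})
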