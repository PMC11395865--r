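test_that("enhancement curves honour their anchors", {
  tumor <- tissue_kinetics("t", 80, 60, "gamma", tp = 5, shape = 1.5)
  scar <- tissue_kinetics("s", 70, 70, "satexp", tau = 12)
  flat <- tissue_kinetics("n", 100)
  # f(0) = 0: baseline exactly at injection time
  expect_identical(enhancement(tumor, 0), 80)
  expect_identical(enhancement(scar, 0), 70)
  expect_identical(enhancement(flat, 0), 100)
  # fast-peaking tumor declines from the early to the late scan
  expect_gt(enhancement(tumor, 5), enhancement(tumor, 20))
  # the curve peaks at tp
  tt <- seq(0.5, 30, by = 0.25)
  expect_equal(tt[which.max(enhancement(tumor, tt))], 5)
  # slow scar accumulates through the late scan
  expect_gt(enhancement(scar, 20), enhancement(scar, 5))
  # continuity in t: increments vanish with the step size
  expect_lt(max(abs(diff(enhancement(tumor, seq(0, 30, by = 0.01))))), 0.25)
  expect_lt(max(abs(diff(enhancement(tumor, seq(0, 30, by = 0.001))))), 0.025)
})

test_that("the generator is deterministic under a seed", {
  a <- small_phantom(seed = 77, snr = 15)
  b <- small_phantom(seed = 77, snr = 15)
  expect_identical(a$early$data, b$early$data)
  expect_identical(a$late$data, b$late$data)
  expect_identical(a$rcbv$data, b$rcbv$data)
  c <- small_phantom(seed = 78, snr = 15)
  expect_false(identical(a$early$data, c$early$data))
})

test_that("a null phantom gives identical early and late volumes", {
  flatk <- list(background = tissue_kinetics("background", 0),
                normal = tissue_kinetics("normal", 100),
                enhancing_tumor = tissue_kinetics("enhancing_tumor", 120),
                necrosis_scar = tissue_kinetics("necrosis_scar", 60),
                vessel = tissue_kinetics("vessel", 110))
  ph <- small_phantom(seed = 1, kinetics = flatk, snr = Inf,
                      bias_amplitude = 0)
  expect_identical(ph$early$data, ph$late$data)
  d <- subtract_series(ph$early, ph$late)
  expect_true(all(d$data$data == 0))
})

test_that("truth masks equal the voxelization of the analytic shapes", {
  ph <- generate_phantom(seed = 3, snr = 20,
                         layout = default_layout(tumor_volume_cm3 = 2))
  lay <- default_layout(tumor_volume_cm3 = 2)
  tum <- lay$lesions[[1]]
  # independent voxelization oracle on the same grid
  dims <- dim(ph$early$data); sp <- ph$early$spacing
  org <- ph$early$origin
  co <- which(array(TRUE, dims), arr.ind = TRUE) - 1
  wx <- org[1] + co[, 1] * sp[1]
  wy <- org[2] + co[, 2] * sp[2]
  wz <- org[3] + co[, 3] * sp[3]
  inside <- (wx - tum$center[1])^2 + (wy - tum$center[2])^2 +
    (wz - tum$center[3])^2 <= tum$radius^2
  oracle_count <- sum(inside)
  tumor_truth <- ph$truth$labels == "enhancing_tumor"
  expect_identical(sum(tumor_truth), oracle_count)
  # and the voxelized volume approximates the analytic 2 cm^3 sphere
  expect_lt(abs(sum(tumor_truth) * prod(sp) - 2000) / 2000, 0.1)
})

test_that("wash-out and wash-in truth follows the kinetics sign", {
  ph <- small_phantom(seed = 5, snr = Inf, bias_amplitude = 0)
  d <- ph$early$data - ph$late$data
  expect_true(all(d[ph$truth$washout_mask] > 0))
  expect_true(all(d[ph$truth$washin_mask] < 0))
  expect_false(any(ph$truth$washout_mask & ph$truth$washin_mask))
})

test_that("lesions outside the head are rejected", {
  lay <- small_layout()
  lay$lesions[[1]]$center <- c(90, 0, 0)
  expect_error(generate_phantom(layout = lay, dims = c(48L, 48L, 36L),
                                spacing = c(3, 3, 3)),
               "outside the head")
})

test_that("the synthetic rCBV map is elevated only in vessel and tumor", {
  ph <- small_phantom(seed = 6)
  hot <- ph$truth$labels %in% c("vessel", "enhancing_tumor")
  expect_true(all(ph$rcbv$data[hot] > 1.2))
  expect_true(all(ph$rcbv$data[!hot] <= 1))
})

test_that("pipeline recovery degrades monotonically with noise", {
  snrs <- c(40, 10, 4)
  dices <- vapply(snrs, function(s) {
    ph <- small_phantom(seed = 31, snr = s)
    nm <- normalize_means(ph$early, ph$late)
    fg <- foreground_mask(nm$early)
    d <- subtract_series(nm$early, nm$late, mask = fg)
    cm <- segment_compartments(d)
    dice_coef(cm$washout_mask, ph$truth$washout_mask)
  }, 0)
  expect_true(all(diff(dices) <= 0))
  expect_gt(dices[1], 0.8)
})

test_that("rician noise keeps magnitudes non-negative and near-gaussian at high SNR", {
  ph <- small_phantom(seed = 8, snr = 20, noise = "rician")
  expect_true(all(ph$early$data >= 0))
  phg <- small_phantom(seed = 8, snr = 20, noise = "gaussian")
  fg <- ph$truth$labels != "background"
  expect_lt(abs(mean(ph$early$data[fg]) - mean(phg$early$data[fg])) /
              mean(phg$early$data[fg]), 0.02)
})
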