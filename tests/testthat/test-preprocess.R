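test_that("foreground mask recovers the head ellipsoid", {
  ph <- small_phantom(seed = 2, snr = 20)
  m <- foreground_mask(ph$early)
  truth <- ph$truth$labels != "background"
  expect_gte(dice_coef(m, truth), 0.95)
})

test_that("foreground polarity policy handles inverted contrast", {
  ph <- small_phantom(seed = 2, snr = 20)
  inv <- ph$early
  inv$data <- max(inv$data) - inv$data
  m <- foreground_mask(inv)
  truth <- ph$truth$labels != "background"
  expect_gte(dice_coef(m, truth), 0.9)
})

test_that("constant images have no foreground", {
  expect_error(foreground_mask(volume(array(0, c(5, 5, 5)))), "constant")
})

test_that("normalize_means hits the symmetric target exactly", {
  # forced example: means 200 and 100 -> target 150, scales 0.75 / 1.5
  e <- volume(array(200, c(6, 6, 6)) + 0)
  l <- volume(array(100, c(6, 6, 6)) + 0)
  mask <- array(TRUE, c(6, 6, 6))
  nm <- normalize_means(e, l, mask, mask)
  expect_equal(unname(nm$scale), c(0.75, 1.5))
  expect_equal(nm$target, 150)
  expect_equal(mean(nm$early$data[mask]), 150, tolerance = 1e-9)
  expect_equal(mean(nm$late$data[mask]), 150, tolerance = 1e-9)
  # identical volumes are left untouched
  nm2 <- normalize_means(e, e, mask, mask)
  expect_equal(unname(nm2$scale), c(1, 1))
  # all-zero late volume over the mask is rejected
  z <- volume(array(0, c(6, 6, 6)))
  expect_error(normalize_means(e, z, mask, mask), "zero")
})

test_that("normalize_means equalizes foreground means for random inputs", {
  set.seed(31)
  for (i in 1:10) {
    e <- volume(array(runif(6^3, 50, 250), c(6, 6, 6)))
    l <- volume(array(runif(6^3, 20, 400), c(6, 6, 6)))
    mask <- array(runif(6^3) > 0.3, c(6, 6, 6))
    nm <- normalize_means(e, l, mask, mask)
    m1 <- mean(nm$early$data[mask]); m2 <- mean(nm$late$data[mask])
    expect_lt(abs(m1 - m2) / m1, 1e-6)
  }
})

test_that("bias correction leaves a bias-free phantom nearly unchanged", {
  # structure-free tissue isolates estimator fidelity: with no bias and no
  # parenchymal modulation the field estimate must be ~1 everywhere
  ph <- small_phantom(seed = 4, snr = Inf, bias_amplitude = 0,
                      texture_amplitude = 0)
  bc <- correct_bias(ph$early, shrink = 3)
  fg <- foreground_mask(ph$early)
  rel <- abs(bc$corrected$data[fg] - ph$early$data[fg]) /
    mean(ph$early$data[fg])
  expect_lt(max(rel), 0.02)
})

test_that("bias correction halves the variation induced by a known field", {
  ph <- small_phantom(seed = 6, snr = Inf, bias_amplitude = 0)
  clean <- ph$early$data
  dims <- dim(clean)
  u <- lapply(dims, function(n) seq(-1, 1, length.out = n))
  xg <- array(rep(u[[1]], times = dims[2] * dims[3]), dims)
  yg <- array(rep(rep(u[[2]], each = dims[1]), times = dims[3]), dims)
  field <- 0.8 + 0.4 * (xg^2 + yg^2) / 2   # smooth quadratic in [0.8, 1.2]
  biased <- with(ph, early)
  biased$data <- clean * field
  bc <- correct_bias(biased, shrink = 3)
  fg <- foreground_mask(biased) & clean > 0
  cv <- function(x) stats::sd(x) / mean(x)
  cv_unc <- cv((biased$data / clean)[fg])
  cv_cor <- cv((bc$corrected$data / clean)[fg])
  expect_lt(cv_cor, 0.5 * cv_unc)
  # the multiplicative contract: corrected * field reproduces the input
  expect_equal(bc$corrected$data * bc$field$data, biased$data,
               tolerance = 1e-10)
  expect_true(all(bc$field$data > 0))
})

test_that("shrink 1 and shrink 3 agree within 5% RMS over the foreground", {
  ph <- small_phantom(seed = 8, snr = 50, bias_amplitude = 0.15)
  b3 <- correct_bias(ph$early, shrink = 3)
  b1 <- correct_bias(ph$early, shrink = 1)
  fg <- foreground_mask(ph$early)
  rms <- sqrt(mean((b3$corrected$data[fg] - b1$corrected$data[fg])^2))
  expect_lt(rms / mean(ph$early$data[fg]), 0.05)
})

test_that("bias correction is idempotent within 1% foreground RMS", {
  ph <- small_phantom(seed = 9, snr = 50, bias_amplitude = 0.2)
  b1 <- correct_bias(ph$early, shrink = 3)
  b2 <- correct_bias(b1$corrected, shrink = 3)
  fg <- foreground_mask(ph$early)
  rms <- sqrt(mean((b2$corrected$data[fg] - b1$corrected$data[fg])^2))
  expect_lt(rms / mean(b1$corrected$data[fg]), 0.01)
})

test_that("the estimated field is smooth at the estimation scale", {
  ph <- small_phantom(seed = 10, snr = 20, bias_amplitude = 0.2)
  bc <- correct_bias(ph$early, shrink = 3)
  f <- bc$field$data
  fs <- array(rapidwashout:::cpp_gauss3d(as.vector(f), dim(f), 3), dim(f))
  # judged over the foreground: outside it the field is extrapolated and
  # clamped, which is irrelevant to correction quality
  fg <- erode_mask(foreground_mask(ph$early), 3)
  expect_lt(stats::var((f - fs)[fg]) / stats::var(f[fg]), 0.05)
})

test_that("constant input yields an identity field with a warning flag", {
  v <- volume(array(5, c(6, 6, 6)) + 0)
  expect_warning(bc <- correct_bias(v), "constant")
  expect_equal(bc$flag, "constant-input")
  expect_true(all(bc$field$data == 1))
  expect_equal(bc$corrected$data, v$data)
})
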