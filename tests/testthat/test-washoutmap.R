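test_that("subtraction is voxelwise early minus late with a valid mask", {
  set.seed(41)
  a <- volume(array(runif(6^3, 100, 200), c(6, 6, 6)))
  b <- volume(array(runif(6^3, 100, 200), c(6, 6, 6)))
  d <- subtract_series(a, b)
  expect_equal(d$data$data, a$data - b$data)
  # self-subtraction: zeros, valid everywhere the mask allows
  mask <- array(runif(6^3) > 0.4, c(6, 6, 6))
  d0 <- subtract_series(a, a, mask = mask)
  expect_true(all(d0$data$data == 0))
  expect_identical(d0$valid_mask, mask)
  # the wash-out sign convention: early 150, late 130 gives +20
  e <- volume(array(150, c(2, 2, 2)) + 0)
  l <- volume(array(130, c(2, 2, 2)) + 0)
  expect_true(all(subtract_series(e, l)$data$data == 20))
  # antisymmetry is exact
  expect_equal(subtract_series(b, a)$data$data, -d$data$data)
  # grids must match
  expect_error(subtract_series(a, volume(array(0, c(6, 6, 5)))), "same grid")
})

test_that("NA fill voxels are excluded from the valid mask", {
  a <- volume(array(1, c(4, 4, 4)) + 0)
  b <- a; b$data[1, 1, 1] <- NA
  d <- subtract_series(a, b)
  expect_false(d$valid_mask[1, 1, 1])
  expect_equal(sum(d$valid_mask), 63)
})

test_that("encoding centres zero at 127 and saturates at the clip range", {
  x <- array(0, c(5, 5, 2))
  x[1, 1, 1] <- 10; x[2, 1, 1] <- -10; x[3, 1, 1] <- 5
  d <- make_difference(x)
  m <- encode_map(d)
  expect_equal(m$difference$clip_range, 10)
  expect_equal(m$gray$data[4, 1, 1], 127)       # d = 0
  expect_equal(m$gray$data[1, 1, 1], 255)       # d = +C
  expect_equal(m$gray$data[2, 1, 1], 0)         # d = -C
  # neutral RGB at zero difference; red/green saturate at the clip range
  expect_equal(as.integer(m$rgb$data[4, 1, 1, ]), c(127, 127, 127))
  expect_equal(as.integer(m$rgb$data[1, 1, 1, ]), c(255, 127, 127))
  expect_equal(as.integer(m$rgb$data[2, 1, 1, ]), c(127, 255, 127))
  # decode inverts the zero and +C anchors exactly; -C (gray 0) comes back
  # within one quantization step, the design's error bound
  dec <- decode_map(m)
  expect_equal(dec$data$data[4, 1, 1], 0)
  expect_equal(dec$data$data[1, 1, 1], 10)
  expect_lte(abs(dec$data$data[2, 1, 1] + 10), 10 / 255 * (1 + 1e-12))
})

test_that("a uniform zero difference encodes to flat 127 with a warning", {
  d <- make_difference(array(0, c(4, 4, 4)))
  expect_warning(m <- encode_map(d), "uniform")
  expect_true(all(m$gray$data == 127))
})

test_that("decode/encode round-trip stays within one quantization step", {
  set.seed(42)
  for (i in 1:10) {
    x <- array(rnorm(8^3, sd = runif(1, 0.5, 50)), c(8, 8, 8))
    d <- make_difference(x)
    m <- encode_map(d)
    C <- m$difference$clip_range
    dec <- decode_map(m)
    err <- abs(dec$data$data - pmax(-C, pmin(C, x)))
    expect_lte(max(err), C / 255 * (1 + 1e-12))
  }
  # missing clip range is an error
  d <- make_difference(array(rnorm(27), c(3, 3, 3)))
  fake <- structure(list(difference = d, gray = d$data), class = "washout_map")
  expect_error(decode_map(fake), "clip_range")
})

test_that("encoding of the negated difference is the red/green mirror", {
  set.seed(43)
  x <- array(rnorm(6^3), c(6, 6, 6))
  x <- x - stats::median(x)   # both polarities present
  m_pos <- encode_map(make_difference(x))
  m_neg <- encode_map(make_difference(-x))
  # same clip range (symmetric construction), channel swap exact
  expect_equal(m_neg$difference$clip_range, m_pos$difference$clip_range)
  expect_identical(m_neg$rgb$data[, , , 1], m_pos$rgb$data[, , , 2])
  expect_identical(m_neg$rgb$data[, , , 2], m_pos$rgb$data[, , , 1])
  expect_identical(m_neg$rgb$data[, , , 3], m_pos$rgb$data[, , , 3])
})

test_that("the anatomy underlay keeps color saturation and neutrality", {
  x <- array(0, c(4, 4, 1)); x[1, 1, 1] <- 8; x[2, 1, 1] <- -8
  u <- volume(array(seq(0, 1, length.out = 16), c(4, 4, 1)))
  m <- encode_map(make_difference(x), underlay = u)
  expect_equal(as.integer(m$rgb$data[1, 1, 1, 1]), 255L)  # red saturates
  expect_equal(as.integer(m$rgb$data[2, 1, 1, 2]), 255L)  # green saturates
  neutral <- m$rgb$data[4, 4, 1, ]
  expect_true(all(neutral == neutral[1]) && neutral[1] <= 127)
})
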