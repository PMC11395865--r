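test_that("rigid transforms satisfy the group axioms", {
  set.seed(21)
  for (i in 1:20) {
    a <- rigid_transform(runif(3, -30, 30), runif(3, -20, 20),
                         center = runif(3, -10, 10))
    b <- rigid_transform(runif(3, -30, 30), runif(3, -20, 20),
                         center = a$center)
    # inverse composes to the identity
    id <- compose_transforms(a, invert_transform(a))
    expect_lt(max(abs(id$rotation - diag(3))), 1e-6)
    expect_lt(max(abs(id$translation)), 1e-6)
    # composition agrees with matrix multiplication on points
    pts <- matrix(runif(15, -50, 50), 5)
    expect_equal(transform_points(compose_transforms(a, b), pts),
                 transform_points(a, transform_points(b, pts)),
                 tolerance = 1e-9)
    # rotation stays orthonormal with determinant +1
    expect_lt(max(abs(crossprod(a$rotation) - diag(3))), 1e-9)
    expect_gt(det(a$rotation), 0)
  }
})

test_that("transform sidecar files round-trip the transform", {
  t1 <- rigid_transform(c(3, -2, 5), c(1.5, -4, 2), center = c(10, -5, 3))
  f <- withr::local_tempfile(fileext = ".txt")
  write_transform(t1, f)
  t2 <- read_transform(f)
  expect_equal(transform_matrix(t2), transform_matrix(t1), tolerance = 1e-12)
  expect_equal(t2$center, t1$center)
})

test_that("apply_transform with identity on the same grid is exact", {
  set.seed(5)
  v <- volume(array(rnorm(10^3), c(10, 10, 10)))
  nn <- apply_transform(v, rigid_transform(), v, "nearest")
  expect_identical(nn$data, v$data)
  tl <- apply_transform(v, rigid_transform(), v, "trilinear")
  expect_equal(tl$data, v$data, tolerance = 1e-12)
})

test_that("a one-voxel translation moves a delta spike by one voxel", {
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 1
  v <- volume(a, spacing = c(2, 2, 2))
  # sampling the moving volume at x + 2 mm shifts content one voxel down
  t <- rigid_transform(translation = c(2, 0, 0))
  r <- apply_transform(v, t, v, "nearest", fill = 0)
  expect_equal(which(r$data == 1, arr.ind = TRUE),
               matrix(c(4L, 5L, 5L), 1, dimnames = list(NULL, c("dim1", "dim2", "dim3"))))
})

test_that("transform then inverse round-trips smooth volumes within 2%", {
  ph <- small_phantom(seed = 12, snr = Inf, bias_amplitude = 0)
  sm <- ph$early
  sm$data <- array(rapidwashout:::cpp_gauss3d(as.vector(sm$data), dim(sm$data), 1.5),
                   dim(sm$data))
  t <- rigid_transform(c(3, -2, 4), c(4, -3, 5))
  fwd <- apply_transform(sm, t, sm)
  back <- apply_transform(fwd, invert_transform(t), sm)
  ok <- !is.na(back$data)
  rms <- sqrt(mean((back$data[ok] - sm$data[ok])^2))
  expect_lt(rms / diff(range(sm$data)), 0.02)
})

test_that("registering a volume to itself returns the identity pose", {
  ph <- small_phantom(seed = 13, snr = 20)
  reg <- estimate_rigid(ph$early, ph$early)
  ang <- rapidwashout:::matrix_to_euler(reg$transform$rotation)
  expect_true(reg$converged)
  expect_lt(max(abs(ang)), 0.1)
  expect_lt(max(abs(reg$transform$translation)), 0.1)
})

test_that("a known rigid misalignment is recovered on the phantom", {
  truth <- rigid_transform(c(3, -2, 4), c(3, -4, 2))
  ph <- small_phantom(seed = 14, snr = 20, transform = truth)
  reg <- estimate_rigid(ph$early, ph$late)
  expect_true(reg$converged)
  brain <- ph$truth$labels != "background"
  disp <- mean_displacement(reg$transform, truth, ph$early, brain)
  expect_lt(disp / ph$early$spacing[1], 1)
  # never worse than the identity pose
  expect_lte(reg$cost, reg$cost_identity)
})

test_that("degenerate registration inputs are rejected", {
  flat <- volume(array(1, c(10, 10, 10)) + 0)
  ph <- small_phantom(seed = 15, snr = 20)
  expect_error(estimate_rigid(flat, ph$early), "constant")
  # disjoint fields of view: same data, far-apart origins
  far <- ph$early
  far$origin <- far$origin + c(1000, 0, 0)
  expect_error(estimate_rigid(ph$early, far), "overlap")
})
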