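# shared fixtures and oracles, all built in code at test time

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# mean displacement (mm) between two rigid transforms over sampled points
mean_displacement <- function(est, truth, vol, mask, n = 3000L) {
  idx <- which(mask, arr.ind = TRUE) - 1
  set.seed(424242)
  pts <- voxel_to_world(vol, idx[sample(nrow(idx), min(n, nrow(idx))), ])
  mean(sqrt(rowSums((transform_points(est, pts) -
                       transform_points(truth, pts))^2)))
}

# a difference object built directly from an array (unit spacing)
make_difference <- function(data, valid = NULL, spacing = c(1, 1, 1)) {
  v <- volume(data, spacing = spacing)
  structure(list(data = v,
                 valid_mask = if (is.null(valid)) array(TRUE, dim(data)) else valid,
                 clip_range = NULL),
            class = "washout_difference")
}

# solid sphere mask on a grid (voxel units, 0-based centers)
sphere_mask <- function(dims, center, radius) {
  co <- which(array(TRUE, dims), arr.ind = TRUE) - 1
  array((co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
          (co[, 3] - center[3])^2 <= radius^2, dims)
}

# independent ICC(2,k) oracle: ANOVA sums of squares by definition
icc2k_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (m[i, j] - row_m[i] - col_m[j] + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

# independent Pearson oracle from the covariance definition
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# compact layout whose head fits a 48 x 48 x 36 grid at 3 mm spacing
small_layout <- function(tumor_volume_cm3 = 4) {
  r_t <- (3 * tumor_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  list(head = list(center = c(0, 0, 0), radii = c(58, 64, 48)),
       lesions = list(
         list(class = "enhancing_tumor", shape = "sphere",
              center = c(22, 8, 6), radius = r_t),
         list(class = "necrosis_scar", shape = "sphere",
              center = c(-25, -10, 0), radius = 11),
         list(class = "vessel", shape = "cylinder",
              center = c(0, -35, 0), radius = 2.5, axis = 3,
              half_length = 28)))
}

# small fast phantom for unit tests that do not need the default grid
small_phantom <- function(seed = 1, ...) {
  generate_phantom(dims = c(48L, 48L, 36L), spacing = c(3, 3, 3),
                   layout = small_layout(), seed = seed, ...)
}
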