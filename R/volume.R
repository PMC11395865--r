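#' 3D image volume with world geometry
#'
#' The package's internal image container: a 3D numeric array together with
#' voxel spacing (mm), the world position of voxel (0,0,0) and a 3x3
#' direction-cosine matrix. World coordinates follow a right-handed RAS-like
#' convention in millimetres; DICOM (LPS) geometry is converted at the
#' reading boundary. Voxel indices are 0-based in all geometry math: the
#' world position of voxel (i, j, k) is
#' `origin + orientation %*% (spacing * c(i, j, k))`.
#'
#' The array axis order is fixed: the first axis is the fastest-varying
#' in-plane direction (DICOM column index), the second the in-plane row
#' index, the third the slice index.
#'
#' @param data numeric 3D array (any intensity units).
#' @param spacing numeric length-3, voxel edge lengths in mm; all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param orientation 3x3 orthonormal direction-cosine matrix; columns are
#'   the world directions of the three array axes.
#' @param meta optional named list of acquisition metadata (series time,
#'   modality, patient ID, ...).
#' @return an object of class `washout_volume`.
#' @examples
#' v <- volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 2))
#' voxel_volume(v)  # 2 mm^3
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   orientation = diag(3), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L || any(dim(data) == 0L))
    stop("volume: 'data' must be a non-empty 3D array")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- as.matrix(orientation)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume: 'spacing' must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume: 'origin' must be 3 finite values")
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("volume: 'orientation' must be a 3x3 orthonormal matrix (tol 1e-6)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = orientation, meta = meta),
            class = "washout_volume")
}

#' @export
print.washout_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<washout_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, intensity range [%s, %s]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              signif(min(x$data, na.rm = TRUE), 5),
              signif(max(x$data, na.rm = TRUE), 5)))
  invisible(x)
}

#' @export
dim.washout_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "washout_volume")

#' Voxel volume in cubic millimetres
#' @param vol a [volume()].
#' @return scalar, product of the three spacings (mm^3).
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Map 0-based voxel indices to world coordinates
#'
#' @param vol a [volume()].
#' @param idx numeric matrix (n x 3) of 0-based voxel indices, or a length-3
#'   vector.
#' @return n x 3 matrix of world positions in mm.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind_idx(idx)
  t(vol$orientation %*% (t(idx) * vol$spacing) + vol$origin)
}

#' Map world coordinates to continuous 0-based voxel indices
#' @param vol a [volume()].
#' @param pts n x 3 matrix of world positions (mm), or a length-3 vector.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind_idx(pts)
  t((t(vol$orientation) %*% (t(pts) - vol$origin)) / vol$spacing)
}

rbind_idx <- function(x) matrix(as.numeric(x), ncol = 3)

# 4x4 homogeneous voxel(0-based) -> world matrix
voxel_world_matrix <- function(vol) {
  m <- diag(4)
  m[1:3, 1:3] <- vol$orientation %*% diag(vol$spacing)
  m[1:3, 4] <- vol$origin
  m
}

# world -> voxel(0-based), inverse of voxel_world_matrix
world_voxel_matrix <- function(vol) solve(voxel_world_matrix(vol))

#' Do two volumes live on the same grid?
#' @param a,b volumes.
#' @param tol geometric tolerance in mm.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

#' World center of a volume's grid
#' @param vol a [volume()].
#' @return length-3 world position (mm) of the grid center.
#' @export
grid_center <- function(vol) {
  drop(voxel_to_world(vol, (dim(vol$data) - 1) / 2))
}

#' RGB volume (three 8-bit channels per voxel)
#'
#' Container for color renderings: a 4D array `x by y by z by 3` of integer
#' channel values in `[0, 255]`, with the same world geometry as [volume()].
#'
#' @param data numeric/integer 4D array, last dimension 3 (R, G, B),
#'   values in `[0, 255]`.
#' @inheritParams volume
#' @return an object of class `washout_rgb_volume`.
#' @export
rgb_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = diag(3), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 4L || dim(data)[4] != 3L)
    stop("rgb_volume: 'data' must be a 4D array with 3 channels")
  if (any(data < 0 | data > 255, na.rm = TRUE) || anyNA(data))
    stop("rgb_volume: channel values must lie in [0, 255]")
  if (max(abs(data - round(data))) > 0)
    stop("rgb_volume: channel values must be integers")
  geom <- volume(array(0, dim(data)[1:3]), spacing, origin, orientation)
  structure(list(data = array(as.integer(round(data)), dim(data)),
                 spacing = geom$spacing, origin = geom$origin,
                 orientation = geom$orientation, meta = meta),
            class = "washout_rgb_volume")
}

#' @export
print.washout_rgb_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<washout_rgb_volume> %d x %d x %d voxels x 3 channels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

is_rgb_volume <- function(x) inherits(x, "washout_rgb_volume")

# replace the data array, keeping geometry/meta
with_data <- function(vol, data) {
  vol$data <- data
  vol
}
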