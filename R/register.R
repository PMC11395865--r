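#' Rigid (6-DOF) transform between two volumes
#'
#' Represents the mapping `y = R (x - c) + c + t` of world points (mm),
#' with rotation matrix `R`, rotation center `c` and translation `t`.
#' Angles follow the intrinsic Z-Y-X Euler convention,
#' `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`, in degrees.
#'
#' @param rotation either a length-3 vector of Euler angles (degrees,
#'   order rx, ry, rz) or a 3x3 rotation matrix.
#' @param translation length-3 translation in mm.
#' @param center length-3 rotation center in world mm.
#' @return an object of class `washout_rigid`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  R <- if (is.matrix(rotation)) rotation else euler_matrix(rotation)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rigid_transform: rotation must be orthonormal with determinant +1")
  structure(list(rotation = R, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "washout_rigid")
}

euler_matrix <- function(deg) {
  a <- deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Euler angles (degrees) back from a rotation matrix (Z-Y-X convention)
matrix_to_euler <- function(R) {
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' @export
print.washout_rigid <- function(x, ...) {
  cat(sprintf("<washout_rigid> rotation (%s) deg, translation (%s) mm\n",
              paste(signif(matrix_to_euler(x$rotation), 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
  cat(sprintf("  center (%s) mm\n", paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

#' Apply a rigid transform to world points
#' @param t a [rigid_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of world points (mm).
#' @return n x 3 matrix of mapped points.
#' @export
transform_points <- function(t, pts) {
  pts <- rbind_idx(pts)
  t(t$rotation %*% (t(pts) - t$center) + t$center + t$translation)
}

#' 4x4 homogeneous matrix of a rigid transform
#' @param t a [rigid_transform()].
#' @return 4x4 matrix acting on world homogeneous coordinates.
#' @export
transform_matrix <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$center + t$translation - t$rotation %*% t$center
  m
}

#' Compose two rigid transforms
#' @param a,b [rigid_transform()]s; the result maps `x` to `a(b(x))`.
#' @return a [rigid_transform()] (center taken from `a`).
#' @export
compose_transforms <- function(a, b) {
  m <- transform_matrix(a) %*% transform_matrix(b)
  R <- m[1:3, 1:3]
  # re-express with a's center: t = m %*% c - R(c - c) ... solve translation
  tr <- m[1:3, 4] - (a$center - R %*% a$center)
  rigid_transform(R, tr, a$center)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return the inverse [rigid_transform()] (same center).
#' @export
invert_transform <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, -Rt %*% t$translation, t$center)
}

#' Resample a volume through a rigid transform onto a reference grid
#'
#' For every voxel of `reference_grid` at world point `p`, the output takes
#' the value of `vol` interpolated at `t(p)` (fixed-to-moving convention:
#' `t` maps reference/fixed world points into `vol`'s world space).
#' Out-of-field voxels are set to `fill` (default `NA`), which downstream
#' subtraction statistics exclude.
#'
#' @param vol moving [volume()].
#' @param t a [rigid_transform()] (fixed world -> moving world).
#' @param reference_grid a [volume()] supplying the output grid.
#' @param interpolation `"trilinear"` (default) or `"nearest"` (for masks).
#' @param fill value assigned outside the moving field of view.
#' @return a [volume()] on the reference grid.
#' @export
apply_transform <- function(vol, t = rigid_transform(),
                            reference_grid = vol,
                            interpolation = c("trilinear", "nearest"),
                            fill = NA_real_) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_volume(vol), inherits(t, "washout_rigid"))
  # output voxel -> fixed world -> moving world -> moving voxel
  M <- world_voxel_matrix(vol) %*% transform_matrix(t) %*%
    voxel_world_matrix(reference_grid)
  out <- cpp_resample_affine(as.vector(vol$data), dim(vol$data),
                             dim(reference_grid$data), M,
                             if (interpolation == "nearest") 0L else 1L,
                             as.double(fill))
  volume(array(out, dim(reference_grid$data)), reference_grid$spacing,
         reference_grid$origin, reference_grid$orientation, vol$meta)
}

## ---- similarity costs -------------------------------------------------

# joint histogram over paired finite values
.joint_hist <- function(a, b, bins, ra, rb) {
  ia <- pmin(bins, pmax(1L, 1L + floor((a - ra[1]) / (ra[2] - ra[1]) * bins)))
  ib <- pmin(bins, pmax(1L, 1L + floor((b - rb[1]) / (rb[2] - rb[1]) * bins)))
  matrix(tabulate(ia + bins * (ib - 1L), bins * bins), bins, bins)
}

# negative similarity (to be minimized) between paired intensity vectors
.similarity_cost <- function(a, b, metric, bins, ra, rb) {
  if (length(a) < 100) return(Inf)
  if (metric == "ncc") {
    r <- suppressWarnings(stats::cor(a, b))
    return(if (is.na(r)) Inf else -abs(r))
  }
  h <- .joint_hist(a, b, bins, ra, rb)
  p <- h / sum(h)
  pa <- rowSums(p); pb <- colSums(p)
  if (metric == "nmi") {
    ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
    hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
    hab <- -sum(p[p > 0] * log(p[p > 0]))
    if (hab <= 0) return(Inf)
    return(-(ha + hb) / hab)
  }
  if (metric == "cr") {
    # correlation ratio of b explained by bins of a
    tot_mean <- sum(pb * seq_len(ncol(p)))
    tot_var <- sum(pb * (seq_len(ncol(p)) - tot_mean)^2)
    if (tot_var <= 0) return(Inf)
    cond <- 0
    for (i in seq_len(nrow(p))) {
      wi <- sum(p[i, ])
      if (wi > 0) {
        mi <- sum(p[i, ] * seq_len(ncol(p))) / wi
        cond <- cond + wi * sum(p[i, ] * (seq_len(ncol(p)) - mi)^2) / wi
      }
    }
    return(-(1 - cond / tot_var))
  }
  stop("unknown metric ", metric)
}

# Gaussian-smoothed, integer-factor downsampled copy for one pyramid level
.pyramid_level <- function(vol, factor, sigma = factor / 2) {
  sigma <- max(sigma, if (factor > 1) factor / 2 else 0)
  sm <- if (sigma > 0)
    array(cpp_gauss3d(as.vector(vol$data), dim(vol$data), sigma),
          dim(vol$data))
  else vol$data
  if (factor <= 1)
    return(volume(sm, vol$spacing, vol$origin, vol$orientation))
  idx <- lapply(dim(vol$data), function(n) seq(1L, n, by = factor))
  volume(sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         vol$spacing * factor, vol$origin, vol$orientation)
}

# matching subsampling of a logical mask (no smoothing)
.pyramid_mask <- function(mask, factor) {
  if (factor <= 1) return(mask)
  idx <- lapply(dim(mask), function(n) seq(1L, n, by = factor))
  mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Estimate the rigid transform aligning two volumes
#'
#' Multi-resolution (coarse-to-fine, three levels by default) rigid
#' registration by direct search (Nelder-Mead) over the 6 pose parameters,
#' minimizing a negative similarity between the fixed volume and the moving
#' volume resampled through the candidate pose. Default similarity is
#' normalized mutual information; correlation ratio (`"cr"`) and absolute
#' correlation (`"ncc"`) are alternatives. Background air is excluded:
#' moving voxels outside the moving foreground are set to `NA` before
#' resampling and the cost is computed over fixed-foreground voxels with
#' valid moving intensities.
#'
#' Initialization is deterministic: the translation starts at the
#' difference of the two foreground centers of mass, and the coarsest
#' level scans a fixed grid of rotation offsets (`rotation_grid` per
#' axis), refining the best few candidates by Nelder-Mead. Each level
#' runs `restarts` Nelder-Mead passes (a restart re-expands the simplex
#' around the incumbent). The whole search involves no randomness, so
#' results are bit-reproducible for fixed inputs and settings.
#'
#' @param fixed,moving [volume()]s; the returned transform maps fixed-world
#'   points into moving-world space, so
#'   `apply_transform(moving, t, fixed)` aligns the moving volume to the
#'   fixed grid.
#' @param mask optional logical mask on the fixed grid restricting the cost.
#' @param metric `"nmi"` (default), `"cr"` or `"ncc"`.
#' @param levels integer vector of downsampling factors, coarse to fine.
#' @param smoothing Gaussian sigma (voxels) applied per level before
#'   downsampling; the finest level gets light smoothing to tame noise in
#'   the joint histogram.
#' @param bins joint-histogram bins.
#' @param maxit Nelder-Mead iteration cap per level (recycled).
#' @param restarts Nelder-Mead restarts per level.
#' @param rotation_grid rotation offsets (degrees, per axis) scanned at the
#'   coarsest level.
#' @return list with `transform` ([rigid_transform()]), `cost`,
#'   `cost_identity`, `converged` (logical: final cost not worse than
#'   identity; otherwise the identity is returned with `converged = FALSE`)
#'   and `settings`.
#' @export
estimate_rigid <- function(fixed, moving, mask = NULL,
                           metric = c("nmi", "cr", "ncc"),
                           levels = c(4L, 2L, 1L), smoothing = c(2, 1, 0.7),
                           bins = 32L, maxit = c(250L, 250L, 150L),
                           restarts = 2L,
                           rotation_grid = c(-4, -2, 0, 2, 4)) {
  metric <- match.arg(metric)
  stopifnot(is_volume(fixed), is_volume(moving))
  if (stats::sd(fixed$data, na.rm = TRUE) == 0 ||
      stats::sd(moving$data, na.rm = TRUE) == 0)
    stop("estimate_rigid: constant input volume")
  ffg <- if (is.null(mask)) foreground_mask(fixed) else mask
  mfg <- foreground_mask(moving)
  mov_masked <- with_data(moving, ifelse(mfg, moving$data, NA_real_))
  center <- grid_center(fixed)
  maxit <- rep_len(maxit, length(levels))
  smoothing <- rep_len(smoothing, length(levels))
  ra <- stats::quantile(fixed$data[ffg], c(0.01, 0.99), names = FALSE)
  rb <- stats::quantile(moving$data[mfg], c(0.01, 0.99), names = FALSE)
  if (diff(ra) <= 0 || diff(rb) <= 0)
    stop("estimate_rigid: degenerate intensity range")

  cost_at <- function(par, fx, mv, fmask) {
    t <- rigid_transform(par[1:3], par[4:6], center)
    res <- apply_transform(mv, t, fx, "trilinear", NA_real_)
    sel <- fmask & !is.na(res$data)
    .similarity_cost(fx$data[sel], res$data[sel], metric, bins, ra, rb)
  }

  # empty-overlap guard at the identity pose
  id_res <- apply_transform(mov_masked, rigid_transform(center = center),
                            fixed, "trilinear", NA_real_)
  if (!any(ffg & !is.na(id_res$data)))
    stop("estimate_rigid: foregrounds do not overlap at the identity pose")

  # center-of-mass translation initialization (fixed -> moving world)
  com <- function(vol, m)
    colMeans(voxel_to_world(vol, which(m, arr.ind = TRUE) - 1))
  par0 <- c(0, 0, 0, com(moving, mfg) - com(fixed, ffg))

  # beam search through the pyramid: the rotation-grid scan at the coarsest
  # level yields several candidate basins, each refined per level; the beam
  # narrows to the single best pose only at the finest level, so a
  # misleading coarse-level optimum cannot commit the search early
  beam <- list(par0)
  for (li in seq_along(levels)) {
    f <- levels[li]
    fx <- .pyramid_level(fixed, f, smoothing[li])
    mv_raw <- .pyramid_level(moving, f, smoothing[li])
    mfg_lvl <- .pyramid_mask(mfg, f)
    mv <- with_data(mv_raw, ifelse(mfg_lvl, mv_raw$data, NA_real_))
    fmask <- .pyramid_mask(ffg, f)
    fn <- function(p) cost_at(p, fx, mv, fmask)
    if (li < length(levels)) {
      # rotation-grid scan at every non-final level: the coarsest level's
      # cost landscape can rank the wrong basin best, so the scan is
      # repeated where the landscape is more trustworthy
      # scans always pivot on the center-of-mass translation: it is nearly
      # unbiased (rotation about the COM barely moves it), whereas an
      # incumbent's translation may be compensating a wrong rotation
      tr_ref <- par0[4:6]
      grid <- as.matrix(expand.grid(rotation_grid, rotation_grid,
                                    rotation_grid))
      vals <- apply(grid, 1, function(r) fn(c(r, tr_ref)))
      scan <- lapply(order(vals)[1:3], function(i) c(grid[i, ], tr_ref))
      beam <- if (li == 1L) scan else c(beam, scan)
    }
    if (li == length(levels) && length(beam) > 1L) {
      # candidate basins can be separated by less than the cost noise at
      # lower resolutions; one full-resolution evaluation each decides
      beam <- beam[order(vapply(beam, fn, 0))[1L]]
    }
    refined <- lapply(beam, function(p) {
      for (r in seq_len(restarts))
        p <- stats::optim(p, fn, method = "Nelder-Mead",
                          control = list(maxit = maxit[li],
                                         reltol = 1e-9))$par
      list(par = p, value = fn(p))
    })
    ord <- order(vapply(refined, `[[`, 0, "value"))
    beam <- lapply(refined[ord[seq_len(min(3L, length(ord)))]], `[[`, "par")
  }
  par <- beam[[1L]]
  final_cost <- cost_at(par, fixed, mov_masked, ffg)
  id_cost <- cost_at(c(0, 0, 0, 0, 0, 0), fixed, mov_masked, ffg)
  settings <- list(metric = metric, levels = levels, smoothing = smoothing,
                   bins = bins, maxit = maxit, restarts = restarts,
                   rotation_grid = rotation_grid)
  if (!is.finite(final_cost) || final_cost > id_cost) {
    return(list(transform = rigid_transform(center = center),
                cost = id_cost, cost_identity = id_cost, converged = FALSE,
                settings = settings))
  }
  list(transform = rigid_transform(par[1:3], par[4:6], center),
       cost = final_cost, cost_identity = id_cost, converged = TRUE,
       settings = settings)
}

#' Write / read a rigid transform as a plain-text 4x4 matrix sidecar
#'
#' The file holds a one-line convention header followed by the 4x4
#' homogeneous matrix (world mm, fixed-to-moving).
#'
#' @param t a [rigid_transform()].
#' @param file path.
#' @param center rotation center to restore on read.
#' @return `file` (write) or a [rigid_transform()] (read).
#' @export
write_transform <- function(t, file) {
  m <- transform_matrix(t)
  hdr <- sprintf("# rigid transform, 4x4 homogeneous, world mm, fixed->moving, center %s",
                 paste(signif(t$center, 10), collapse = " "))
  writeLines(c(hdr, apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))), file)
  invisible(file)
}

#' @rdname write_transform
#' @export
read_transform <- function(file) {
  lines <- readLines(file)
  center <- as.numeric(strsplit(sub(".*center ", "", lines[1]), " ")[[1]])
  m <- do.call(rbind, lapply(lines[2:5], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  R <- m[1:3, 1:3]
  tr <- m[1:3, 4] - (center - R %*% center)
  rigid_transform(R, tr, center)
}
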