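#' Head/brain foreground mask by histogram thresholding
#'
#' Otsu's threshold on a 256-bin intensity histogram separates head from
#' air; the mask is the polarity whose above/below-threshold side occupies
#' the smaller volume fraction (so an inverted-contrast image — bright
#' background, dark head — still yields the head region), reduced to its
#' largest 26-connected component, with interior holes filled (background
#' components not touching the grid border are absorbed).
#'
#' @param vol a [volume()].
#' @return logical 3D array, `TRUE` on the foreground.
#' @export
foreground_mask <- function(vol) {
  stopifnot(is_volume(vol))
  x <- vol$data
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("foreground_mask: constant image has no foreground")
  thr <- otsu_threshold(x)
  m <- x > thr
  m[is.na(m)] <- FALSE
  # polarity policy: foreground is the minority side of the threshold
  if (mean(m) > 0.5) m <- !m & !is.na(x)
  m <- largest_component(m)
  fill_holes(m)
}

# Otsu's method on a 256-bin histogram (maximize between-class variance)
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x)
  h <- tabulate(pmin(256L, 1L + floor(255 * (x - rng[1]) / diff(rng))), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + (k / 256) * diff(rng)
}

largest_component <- function(mask) {
  lab <- cpp_label3d(as.logical(mask), dim(mask))
  n <- attr(lab, "ncomp")
  if (n == 0L) return(array(FALSE, dim(mask)))
  sizes <- tabulate(lab[lab > 0L], n)
  array(lab == which.max(sizes), dim(mask))
}

#' Erode a binary mask
#'
#' Iterative 6-neighbour erosion (voxels outside the grid count as
#' background). Used to peel the partial-volume rim off the foreground
#' before subtraction statistics: after resampling, voxels on the head
#' boundary mix tissue and air intensities and their difference values are
#' meaningless.
#'
#' @param mask logical 3D array.
#' @param voxels number of erosion iterations (peeled shells).
#' @return logical array of the same shape.
#' @export
erode_mask <- function(mask, voxels = 2L) {
  d <- dim(mask)
  for (i in seq_len(voxels)) {
    out <- mask
    out[1, , ] <- FALSE; out[d[1], , ] <- FALSE
    out[, 1, ] <- FALSE; out[, d[2], ] <- FALSE
    out[, , 1] <- FALSE; out[, , d[3]] <- FALSE
    out[2:(d[1] - 1), , ] <- out[2:(d[1] - 1), , ] &
      mask[1:(d[1] - 2), , ] & mask[3:d[1], , ]
    out[, 2:(d[2] - 1), ] <- out[, 2:(d[2] - 1), ] &
      mask[, 1:(d[2] - 2), ] & mask[, 3:d[2], ]
    out[, , 2:(d[3] - 1)] <- out[, , 2:(d[3] - 1)] &
      mask[, , 1:(d[3] - 2)] & mask[, , 3:d[3]]
    mask <- out
  }
  mask
}

# fill interior holes: background components not touching the border
fill_holes <- function(mask) {
  bg <- !mask
  lab <- cpp_label3d(as.logical(bg), dim(mask))
  n <- attr(lab, "ncomp")
  if (n == 0L) return(mask)
  lab <- array(lab, dim(mask))
  d <- dim(mask)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  mask | (lab > 0L & !(lab %in% border_labels))
}

#' Normalize two series to the same mean intensity
#'
#' Each series is linearly scaled so its mean over its own foreground mask
#' equals the common target: the arithmetic mean of the two original
#' foreground means. This symmetric choice privileges neither acquisition;
#' the returned scale factors let either single-reference convention be
#' recovered. Masked (not whole-grid) means are used because background air
#' would otherwise dominate the scaling.
#'
#' @param early,late [volume()]s (normalization precedes resampling, so the
#'   grids need not match; each mask lives in its own volume's space).
#' @param mask_early,mask_late logical foreground masks; computed with
#'   [foreground_mask()] when omitted.
#' @return list with elements `early`, `late` (scaled volumes), `scale`
#'   (length-2 numeric: factors applied to early and late) and `target`
#'   (the common mean).
#' @export
normalize_means <- function(early, late, mask_early = NULL, mask_late = NULL) {
  stopifnot(is_volume(early), is_volume(late))
  if (is.null(mask_early)) mask_early <- foreground_mask(early)
  if (is.null(mask_late)) mask_late <- foreground_mask(late)
  if (!any(mask_early) || !any(mask_late))
    stop("normalize_means: empty foreground mask")
  m1 <- mean(early$data[mask_early], na.rm = TRUE)
  m2 <- mean(late$data[mask_late], na.rm = TRUE)
  if (!is.finite(m1) || !is.finite(m2) || m1 == 0 || m2 == 0)
    stop("normalize_means: zero or undefined mean over the mask")
  target <- (m1 + m2) / 2
  scale <- c(early = target / m1, late = target / m2)
  list(early = with_data(early, early$data * scale[1]),
       late = with_data(late, late$data * scale[2]),
       scale = scale, target = target)
}

#' Multiplicative bias-field correction
#'
#' Estimates the smooth multiplicative intensity inhomogeneity (bias field)
#' of an MRI volume and divides it out. The field is modelled in the log
#' domain as a tensor-product polynomial (degree 2 per axis) fitted to the
#' foreground intensities by iteratively reweighted least squares (Tukey
#' biweight), which keeps focal tissue structure from being absorbed into
#' the field. Estimation runs on a grid downsampled by `shrink` along each
#' axis; the fitted analytic field is then evaluated at full resolution and
#' normalized to mean 1 over the foreground, so the corrected volume keeps
#' the input's overall intensity level.
#'
#' @param vol a [volume()].
#' @param shrink integer >= 1, downsampling factor during estimation
#'   (default 3).
#' @param mask optional logical foreground mask; computed when omitted.
#' @param degree per-axis polynomial degree of the log-field model.
#' @param iterations IRLS iterations.
#' @return an object of class `washout_bias` with elements `corrected`
#'   (volume), `field` (volume, strictly positive, mean 1 over the mask),
#'   `shrink`, and `flag` (`"ok"` or `"constant-input"`).
#' @export
correct_bias <- function(vol, shrink = 3L, mask = NULL, degree = 2L,
                         iterations = 3L) {
  stopifnot(is_volume(vol), shrink >= 1)
  rng <- range(vol$data, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("correct_bias: constant image; returning identity field")
    return(structure(list(corrected = vol,
                          field = with_data(vol, array(1, dim(vol$data))),
                          shrink = as.integer(shrink), flag = "constant-input"),
                     class = "washout_bias"))
  }
  if (is.null(mask)) mask <- foreground_mask(vol)
  d <- dim(vol$data)
  sub <- lapply(d, function(n) seq(1L, n, by = as.integer(shrink)))
  xs <- vol$data[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  ms <- mask[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  keep <- which(ms & is.finite(xs) & xs > 0)
  if (length(keep) < 50L)
    stop("correct_bias: too few positive foreground voxels to fit a field")
  # normalized [-1, 1] full-grid coordinates of the retained low-res voxels
  co <- arrayInd(keep, dim(xs))
  full_idx <- vapply(1:3, function(a) sub[[a]][co[, a]], numeric(nrow(co)))
  norm_co <- sweep(sweep(full_idx - 1, 2, pmax(1, d - 1) / 2, "/"), 2, 1, "-")
  basis <- .poly_basis_3d(norm_co, degree)
  y <- log(xs[keep])
  w <- rep(1, length(y))
  for (it in seq_len(iterations)) {
    fit <- lm.wfit(basis, y, w)
    r <- y - basis %*% fit$coefficients
    s <- stats::median(abs(r)) * 1.4826
    if (s <= .Machine$double.eps) break
    u <- pmin(1, abs(r) / (4.685 * s))
    w <- drop((1 - u^2)^2)
  }
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  # evaluate the fitted log-field analytically on the full grid
  full_co <- as.matrix(expand.grid(x = (seq_len(d[1]) - 1) / pmax(1, (d[1] - 1) / 2) - 1,
                                   y = (seq_len(d[2]) - 1) / pmax(1, (d[2] - 1) / 2) - 1,
                                   z = (seq_len(d[3]) - 1) / pmax(1, (d[3] - 1) / 2) - 1))
  logf <- array(.poly_basis_3d(full_co, degree) %*% beta, d)
  field <- exp(logf)
  # the fit is only meaningful on the foreground: clamp the extrapolated
  # background/corner values into the range observed over the mask, else
  # the polynomial can explode there and wreck background intensities
  rng_mask <- range(field[mask])
  field <- pmin(pmax(field, rng_mask[1]), rng_mask[2])
  field <- field / mean(field[mask])
  structure(list(corrected = with_data(vol, vol$data / field),
                 field = with_data(vol, field),
                 shrink = as.integer(shrink), flag = "ok"),
            class = "washout_bias")
}

#' @export
print.washout_bias <- function(x, ...) {
  cat(sprintf("<washout_bias> shrink %d, field range [%s, %s], flag %s\n",
              x$shrink, signif(min(x$field$data), 4),
              signif(max(x$field$data), 4), x$flag))
  invisible(x)
}

# tensor-product polynomial design matrix over n x 3 coordinates in [-1,1]
.poly_basis_3d <- function(co, degree) {
  px <- outer(co[, 1], 0:degree, "^")
  py <- outer(co[, 2], 0:degree, "^")
  pz <- outer(co[, 3], 0:degree, "^")
  n <- nrow(co)
  k <- (degree + 1L)^3
  out <- matrix(0, n, k)
  col <- 1L
  for (iz in seq_len(degree + 1L))
    for (iy in seq_len(degree + 1L))
      for (ix in seq_len(degree + 1L)) {
        out[, col] <- px[, ix] * py[, iy] * pz[, iz]
        col <- col + 1L
      }
  out
}
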