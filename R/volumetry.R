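#' Segment wash-out and wash-in compartments from a difference volume
#'
#' Thresholds the signed difference symmetrically: wash-out voxels exceed
#' `+threshold`, wash-in voxels fall below `-threshold`. Each compartment
#' is cleaned by removing 26-connected components smaller than
#' `min_component_mm3`. When no threshold is given it defaults to
#' `k * sigma_bg`, where `sigma_bg` is a robust noise scale of the
#' difference over the valid mask (median absolute deviation about zero,
#' scaled to the Gaussian sigma); the lesion compartments occupy a small
#' fraction of the brain, so the MAD is driven by normal-appearing tissue.
#'
#' @param diff a `washout_difference` from [subtract_series()].
#' @param threshold positive scalar in difference units; `NULL` for the
#'   `k * sigma_bg` default.
#' @param k multiplier for the automatic noise-scaled threshold.
#' @param min_component_mm3 minimum connected-component volume retained
#'   (default 50 mm^3: at the default 3-sigma threshold roughly 0.1% of
#'   brain voxels exceed it by chance, so 26-connected chance clusters of
#'   two or three voxels are common while clusters of this size are
#'   vanishingly rare; 0.05 cm^3 is also far below any reportable lesion).
#' @param roi optional logical restriction mask (raters' lesion
#'   neighbourhood); must be non-empty.
#' @return an object of class `washout_compartments`: `washout_mask`,
#'   `washin_mask` (logical arrays), `threshold`, `min_component_mm3`,
#'   `spacing`, `roi` (or `NULL`).
#' @export
segment_compartments <- function(diff, threshold = NULL, k = 3,
                                 min_component_mm3 = 50, roi = NULL) {
  stopifnot(inherits(diff, "washout_difference"))
  d <- diff$data$data
  valid <- diff$valid_mask
  if (!is.null(roi)) {
    if (!any(roi)) stop("segment_compartments: empty roi")
    valid <- valid & roi
  }
  if (is.null(threshold)) {
    sigma <- stats::mad(d[diff$valid_mask], center = 0)
    if (sigma == 0) {
      # degenerate (e.g. identical series): nothing can exceed noise
      warning("segment_compartments: zero noise scale in the difference; ",
              "compartments will be empty")
      sigma <- .Machine$double.eps
    }
    threshold <- k * sigma
  }
  if (!is.finite(threshold) || threshold <= 0)
    stop("segment_compartments: threshold must be positive")
  spacing <- diff$data$spacing
  vox <- prod(spacing)
  clean <- function(mask) {
    mask[is.na(mask)] <- FALSE
    lab <- cpp_label3d(as.logical(mask), dim(mask))
    n <- attr(lab, "ncomp")
    if (n == 0L) return(array(FALSE, dim(mask)))
    sizes <- tabulate(lab[lab > 0L], n) * vox
    keep <- which(sizes >= min_component_mm3)
    array(array(lab, dim(mask)) %in% keep & mask, dim(mask))
  }
  washout <- clean(d > threshold & valid)
  washin <- clean(d < -threshold & valid)
  structure(list(washout_mask = washout, washin_mask = washin,
                 threshold = threshold, min_component_mm3 = min_component_mm3,
                 spacing = spacing, roi = roi,
                 geometry = diff$data),
            class = "washout_compartments")
}

#' Measure compartment volumes and the wash-out ratio
#'
#' Volumes are exact voxel counts times the voxel volume. The wash-out
#' ratio is wash-out volume / (wash-out volume + wash-in volume); when both
#' compartments are empty it is undefined and flagged. Each 26-connected
#' component of either compartment yields one per-lesion row with its
#' centroid in world mm.
#'
#' @param masks a `washout_compartments` from [segment_compartments()].
#' @param spacing voxel spacing in mm (defaults to the spacing carried by
#'   `masks`).
#' @return an object of class `washout_volumetry`: `washout_mm3`,
#'   `washin_mm3`, `washout_ratio` (`NA` with `ratio_defined = FALSE` when
#'   undefined), `lesion_count` and `lesions` (data frame: id, compartment,
#'   centroid, volume).
#' @export
measure_compartments <- function(masks, spacing = masks$spacing) {
  stopifnot(inherits(masks, "washout_compartments"))
  vox <- prod(spacing)
  wo <- sum(masks$washout_mask) * vox
  wi <- sum(masks$washin_mask) * vox
  defined <- (wo + wi) > 0
  ratio <- if (defined) wo / (wo + wi) else NA_real_
  lesion_rows <- function(mask, compartment) {
    lab <- cpp_label3d(as.logical(mask), dim(mask))
    n <- attr(lab, "ncomp")
    if (n == 0L) return(NULL)
    lab <- array(lab, dim(mask))
    do.call(rbind, lapply(seq_len(n), function(i) {
      idx <- which(lab == i, arr.ind = TRUE)
      cen0 <- colMeans(idx) - 1       # 0-based voxel centroid
      cw <- if (!is.null(masks$geometry))
        drop(voxel_to_world(masks$geometry, cen0)) else cen0 * spacing
      data.frame(compartment = compartment,
                 centroid_x_mm = cw[1], centroid_y_mm = cw[2],
                 centroid_z_mm = cw[3], volume_mm3 = nrow(idx) * vox)
    }))
  }
  lesions <- rbind(lesion_rows(masks$washout_mask, "washout"),
                   lesion_rows(masks$washin_mask, "washin"))
  if (!is.null(lesions)) {
    lesions <- cbind(id = seq_len(nrow(lesions)), lesions)
    rownames(lesions) <- NULL
  } else {
    lesions <- data.frame(id = integer(), compartment = character(),
                          centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                          centroid_z_mm = numeric(), volume_mm3 = numeric())
  }
  structure(list(washout_mm3 = wo, washin_mm3 = wi, washout_ratio = ratio,
                 ratio_defined = defined, lesion_count = nrow(lesions),
                 lesions = lesions, threshold = masks$threshold),
            class = "washout_volumetry")
}

#' @export
print.washout_volumetry <- function(x, ...) {
  cat(sprintf("<washout_volumetry> wash-out %.1f mm3, wash-in %.1f mm3\n",
              x$washout_mm3, x$washin_mm3))
  cat(if (x$ratio_defined)
    sprintf("  wash-out ratio %.3f over %d lesion component(s)\n",
            x$washout_ratio, x$lesion_count)
    else "  wash-out ratio undefined (both compartments empty)\n")
  invisible(x)
}

#' Perfusion volumetry at an rCBV threshold
#'
#' Segments hyperperfusion as voxels with rCBV above `rcbv_threshold`
#' (default 1.2, in units relative to normal-appearing tissue), optionally
#' intersected with a contrast-enhancement mask. Components whose largest
#' in-plane (single-slice) cross-sectional area does not exceed
#' `min_area_cm2` are discarded — the minimum-lesion-size rule stated as a
#' 2D area criterion (default 0.25 cm^2). Reports the retained mask, its
#' volume, and the maximum rCBV inside it (the per-lesion relative-rCBV
#' summary).
#'
#' @param rcbv a [volume()] of relative CBV values.
#' @param rcbv_threshold scalar threshold (ratio units).
#' @param min_area_cm2 minimum in-plane cross-section per component.
#' @param enhancement_mask optional logical mask of contrast-enhancing
#'   tissue.
#' @return list: `mask` (logical array), `volume_mm3`, `max_rcbv` (`NA`
#'   when the mask is empty), `threshold`, `min_area_cm2`.
#' @export
segment_perfusion <- function(rcbv, rcbv_threshold = 1.2, min_area_cm2 = 0.25,
                              enhancement_mask = NULL) {
  stopifnot(is_volume(rcbv))
  m <- rcbv$data > rcbv_threshold
  m[is.na(m)] <- FALSE
  if (!is.null(enhancement_mask)) m <- m & enhancement_mask
  pixel_area_mm2 <- rcbv$spacing[1] * rcbv$spacing[2]
  min_area_mm2 <- min_area_cm2 * 100
  lab <- cpp_label3d(as.logical(m), dim(m))
  n <- attr(lab, "ncomp")
  keep <- logical(n)
  if (n > 0L) {
    lab <- array(lab, dim(m))
    nslice <- dim(m)[3]
    # largest single-slice cross-section per component
    areas <- matrix(0, n, nslice)
    for (kk in seq_len(nslice)) {
      sl <- lab[, , kk]
      t <- tabulate(sl[sl > 0L], n)
      areas[, kk] <- t * pixel_area_mm2
    }
    keep <- apply(areas, 1, max) > min_area_mm2
    m <- lab > 0L & array(keep[pmax(lab, 1L)], dim(m))
  }
  vol <- sum(m) * prod(rcbv$spacing)
  list(mask = m, volume_mm3 = vol,
       max_rcbv = if (any(m)) max(rcbv$data[m]) else NA_real_,
       threshold = rcbv_threshold, min_area_cm2 = min_area_cm2)
}
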