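#' Read a NIfTI-1 volume
#'
#' Reads `.nii` or `.nii.gz` into the package's [volume()] container. The
#' NIfTI xform (sform when set, else qform) already uses RAS world
#' coordinates, the package's internal convention, so spacing, origin and
#' orientation are taken straight from the 4x4 matrix: spacing as the column
#' norms, orientation as the normalized columns, origin as the translation.
#'
#' @param file path to a NIfTI-1 file.
#' @param nonortho what to do when the stored orientation is not orthonormal
#'   within 1e-6 after normalization: `"orthonormalize"` projects it onto
#'   the nearest rotation/reflection via the polar decomposition (shear is
#'   discarded), `"error"` rejects the file.
#' @return a [volume()].
#' @export
read_nifti <- function(file, nonortho = c("orthonormalize", "error")) {
  nonortho <- match.arg(nonortho)
  if (!file.exists(file)) stop("read_nifti: file not found: ", file)
  if (file.info(file)$size == 0) stop("read_nifti: empty file: ", file)
  img <- tryCatch(RNifti::readNifti(file),
                  error = function(e) stop("read_nifti: malformed NIfTI: ",
                                           conditionMessage(e)))
  x <- RNifti::xform(img, useQuaternionFirst = FALSE)
  a <- as.array(img)
  a <- array(as.vector(a), dim(a))   # strip niftiImage attributes
  if (length(dim(a)) > 3L) {
    if (prod(dim(a)[-(1:3)]) != 1L)
      stop("read_nifti: only 3D volumes are supported")
    a <- array(a, dim(a)[1:3])
  }
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  rot <- x[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0)) stop("read_nifti: degenerate xform (zero spacing)")
  ortho <- sweep(rot, 2, spacing, "/")
  if (max(abs(crossprod(ortho) - diag(3))) > 1e-6) {
    if (nonortho == "error")
      stop("read_nifti: non-orthonormal orientation in ", file)
    sv <- svd(ortho)
    ortho <- sv$u %*% t(sv$v)  # polar factor: nearest orthonormal matrix
  }
  volume(a, spacing = spacing, origin = x[1:3, 4], orientation = ortho,
         meta = list(source = file))
}

#' Write a volume as NIfTI-1
#'
#' The inverse of [read_nifti()]: data, spacing, origin and orientation are
#' stored in the sform (code 2). Writing then reading back is lossless for
#' the data and geometry within float precision.
#'
#' @param vol a [volume()].
#' @param file output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `file`, invisibly.
#' @export
write_nifti <- function(vol, file) {
  stopifnot(is_volume(vol))
  if (!dir.exists(dirname(file)))
    stop("write_nifti: parent directory does not exist: ", dirname(file))
  img <- RNifti::asNifti(vol$data)
  m <- rbind(cbind(vol$orientation %*% diag(vol$spacing), vol$origin),
             c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Write a binary mask as NIfTI (uint8)
#' @param mask logical/0-1 3D array.
#' @param geom a [volume()] providing the grid geometry.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mask_nifti <- function(mask, geom, file) {
  v <- volume(array(as.double(mask), dim(geom$data)), geom$spacing,
              geom$origin, geom$orientation)
  img <- RNifti::asNifti(v$data, datatype = "uint8")
  m <- rbind(cbind(v$orientation %*% diag(v$spacing), v$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, file)
  invisible(file)
}
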