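## Minimal DICOM layer: uncompressed little-endian read (explicit and
## implicit VR, classic single-frame series and simple multi-frame files)
## and a secondary-capture writer for grayscale and RGB result series.
## DICOM stores patient coordinates in LPS; the package's world convention
## is RAS, so the first two axes are sign-flipped at this boundary.

EXPLICIT_LE <- "1.2.840.10008.1.2.1"
IMPLICIT_LE <- "1.2.840.10008.1.2"
SC_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture image

# tag dictionary: name, VR (used for implicit-VR files and for writing)
.dcm_dict <- local({
  d <- rbind(
    c("0002,0010", "TransferSyntaxUID", "UI"),
    c("0008,0008", "ImageType", "CS"),
    c("0008,0016", "SOPClassUID", "UI"),
    c("0008,0018", "SOPInstanceUID", "UI"),
    c("0008,0060", "Modality", "CS"),
    c("0008,103e", "SeriesDescription", "LO"),
    c("0010,0010", "PatientName", "PN"),
    c("0010,0020", "PatientID", "LO"),
    c("0018,0050", "SliceThickness", "DS"),
    c("0018,0088", "SpacingBetweenSlices", "DS"),
    c("0020,000d", "StudyInstanceUID", "UI"),
    c("0020,000e", "SeriesInstanceUID", "UI"),
    c("0020,0011", "SeriesNumber", "IS"),
    c("0020,0013", "InstanceNumber", "IS"),
    c("0020,0032", "ImagePositionPatient", "DS"),
    c("0020,0037", "ImageOrientationPatient", "DS"),
    c("0028,0002", "SamplesPerPixel", "US"),
    c("0028,0004", "PhotometricInterpretation", "CS"),
    c("0028,0006", "PlanarConfiguration", "US"),
    c("0028,0008", "NumberOfFrames", "IS"),
    c("0028,0010", "Rows", "US"),
    c("0028,0011", "Columns", "US"),
    c("0028,0030", "PixelSpacing", "DS"),
    c("0028,0100", "BitsAllocated", "US"),
    c("0028,0101", "BitsStored", "US"),
    c("0028,0102", "HighBit", "US"),
    c("0028,0103", "PixelRepresentation", "US"),
    c("0028,1052", "RescaleIntercept", "DS"),
    c("0028,1053", "RescaleSlope", "DS"),
    c("7fe0,0010", "PixelData", "OW"))
  data.frame(tag = d[, 1], name = d[, 2], vr = d[, 3],
             stringsAsFactors = FALSE)
})

.u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.u32 <- function(raw, pos) {
  # returns NA for the undefined-length marker 0xFFFFFFFF
  b <- as.numeric(raw[pos:(pos + 3L)])
  v <- b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
  if (v == 4294967295) NA_real_ else v
}

.tag_key <- function(group, elem) sprintf("%04x,%04x", group, elem)

# Parse one dataset (raw byte window), collecting dictionary tags.
# Handles explicit and implicit VR little endian, and skips sequences
# (defined or undefined length) recursively.
.parse_dataset <- function(raw, pos, end, implicit, out = list()) {
  short_vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
                 "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL",
                 "US")
  while (pos + 7 <= end) {
    group <- .u16(raw, pos); elem <- .u16(raw, pos + 2L)
    key <- .tag_key(group, elem)
    if (group == 0xFFFE) {  # item / delimiter machinery
      len <- .u32(raw, pos + 4L)
      pos <- pos + 8L
      if (elem == 0xE00D || elem == 0xE0DD) return(list(values = out, pos = pos))
      if (elem == 0xE000) {
        if (is.na(len)) {
          r <- .parse_dataset(raw, pos, end, implicit, list())
          pos <- r$pos
        } else pos <- pos + len
      }
      next
    }
    if (implicit && group != 0x0002) {
      len <- .u32(raw, pos + 4L)
      data_pos <- pos + 8L
      vr <- .dcm_dict$vr[match(key, .dcm_dict$tag)]
      if (is.na(vr)) vr <- "UN"
      if (is.na(len)) vr <- "SQ"  # undefined length implies a sequence here
    } else {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% short_vrs) {
        len <- .u16(raw, pos + 6L)
        data_pos <- pos + 8L
      } else {
        len <- .u32(raw, pos + 8L)
        data_pos <- pos + 12L
      }
    }
    if (vr == "SQ" || is.na(len)) {
      if (is.na(len)) {
        # walk items until the sequence delimitation item
        p <- data_pos
        repeat {
          if (p + 7 > end) stop("read_dicom: truncated sequence")
          g2 <- .u16(raw, p); e2 <- .u16(raw, p + 2L); l2 <- .u32(raw, p + 4L)
          p <- p + 8L
          if (g2 == 0xFFFE && e2 == 0xE0DD) break
          if (g2 == 0xFFFE && e2 == 0xE000) {
            if (is.na(l2)) p <- .parse_dataset(raw, p, end, implicit, list())$pos
            else p <- p + l2
          } else stop("read_dicom: malformed sequence")
        }
        pos <- p
      } else pos <- data_pos + len
      next
    }
    val_raw <- if (len > 0) raw[data_pos:(data_pos + len - 1L)] else raw(0)
    pos <- data_pos + len
    if (key %in% .dcm_dict$tag || group == 0x0002) {
      nm <- .dcm_dict$name[match(key, .dcm_dict$tag)]
      if (is.na(nm)) nm <- key
      out[[nm]] <- .decode_value(val_raw, vr)
    }
  }
  list(values = out, pos = pos)
}

.decode_value <- function(val, vr) {
  str_vrs <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
               "TM", "UI", "UT")
  if (vr %in% str_vrs) {
    s <- rawToChar(val[val != as.raw(0)])
    return(sub("[ ]+$", "", s))
  }
  if (vr == "DS") {
    s <- rawToChar(val[val != as.raw(0)])
    return(as.numeric(strsplit(trimws(s), "\\\\")[[1]]))
  }
  if (vr == "IS") {
    s <- rawToChar(val[val != as.raw(0)])
    return(as.integer(strsplit(trimws(s), "\\\\")[[1]]))
  }
  if (vr == "US") return(readBin(val, "integer", n = length(val) / 2,
                                 size = 2, signed = FALSE, endian = "little"))
  if (vr == "SS") return(readBin(val, "integer", n = length(val) / 2,
                                 size = 2, signed = TRUE, endian = "little"))
  if (vr %in% c("UL", "SL")) return(readBin(val, "integer", n = length(val) / 4,
                                            size = 4, endian = "little"))
  if (vr == "FD") return(readBin(val, "double", n = length(val) / 8,
                                 endian = "little"))
  if (vr == "FL") return(readBin(val, "double", n = length(val) / 4, size = 4,
                                 endian = "little"))
  val  # raw payload (pixel data etc.)
}

# Read one DICOM file into a named list of dictionary attributes.
read_dicom_file <- function(file) {
  raw <- readBin(file, "raw", n = file.info(file)$size)
  if (length(raw) < 140) stop("read_dicom: not a DICOM file: ", file)
  pos <- 1L
  has_preamble <- identical(rawToChar(raw[129:132]), "DICM")
  meta <- list()
  implicit <- FALSE
  if (has_preamble) {
    pos <- 133L
    # file meta group is always explicit VR LE; bounded by its group length
    gl_len <- .u16(raw, pos + 6L)
    gl <- .decode_value(raw[(pos + 8L):(pos + 8L + gl_len - 1L)], "UL")
    meta_end <- pos + 8L + gl_len + gl
    r <- .parse_dataset(raw, pos, meta_end - 1L, implicit = FALSE)
    meta <- r$values
    pos <- meta_end
    ts <- meta$TransferSyntaxUID
    if (!is.null(ts)) {
      if (ts == IMPLICIT_LE) implicit <- TRUE
      else if (ts != EXPLICIT_LE)
        stop("read_dicom: unsupported transfer syntax ", ts, " in ", file)
    }
  } else {
    # headerless stream: sniff explicit VR by checking for a valid VR code
    vr <- rawToChar(raw[5:6])
    implicit <- !grepl("^[A-Z]{2}$", vr)
  }
  out <- .parse_dataset(raw, pos, length(raw), implicit)$values
  out$TransferSyntaxUID <- meta$TransferSyntaxUID
  out
}

.decode_pixels <- function(att, file) {
  need <- c("Rows", "Columns", "BitsAllocated", "PixelData")
  miss <- setdiff(need, names(att))
  if (length(miss))
    stop("read_dicom: missing attributes (", paste(miss, collapse = ", "),
         ") in ", file)
  rows <- att$Rows; cols <- att$Columns
  spp <- if (is.null(att$SamplesPerPixel)) 1L else att$SamplesPerPixel
  nframes <- if (is.null(att$NumberOfFrames)) 1L else att$NumberOfFrames
  bits <- att$BitsAllocated
  n <- as.numeric(rows) * cols * spp * nframes
  px <- att$PixelData
  if (bits == 8) {
    vals <- as.integer(px[seq_len(n)])
  } else if (bits == 16) {
    signed <- !is.null(att$PixelRepresentation) && att$PixelRepresentation == 1
    vals <- readBin(px, "integer", n = n, size = 2, signed = TRUE,
                    endian = "little")
    if (!signed) vals <- ifelse(vals < 0, vals + 65536L, vals)
  } else stop("read_dicom: unsupported BitsAllocated ", bits)
  # stored row-major (columns fastest); planar configuration 0 interleaves
  # samples per pixel
  if (spp == 1L) {
    array(vals, dim = c(cols, rows, nframes))
  } else {
    if (!is.null(att$PlanarConfiguration) && att$PlanarConfiguration == 1)
      stop("read_dicom: planar configuration 1 not supported")
    a <- array(vals, dim = c(spp, cols, rows, nframes))
    aperm(a, c(2, 3, 4, 1))
  }
}

#' Read a DICOM series into a volume
#'
#' Reads all DICOM files of one series from a directory: classic
#' one-file-per-slice series and simple single-file multi-frame objects are
#' both supported (uncompressed little-endian transfer syntaxes). Slices
#' are ordered by their spatial position along the slice normal, never by
#' file name; the rescale slope/intercept is applied; geometry (LPS) is
#' converted to the package's RAS world convention.
#'
#' @param directory path containing exactly one DICOM series.
#' @return a [volume()] for grayscale data, or an [rgb_volume()] when the
#'   series' photometric interpretation is RGB.
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("read_dicom_series: no files in ", directory)
  atts <- lapply(files, read_dicom_file)
  uids <- vapply(atts, function(a)
    if (is.null(a$SeriesInstanceUID)) "<missing>" else a$SeriesInstanceUID, "")
  if (length(unique(uids)) > 1L)
    stop("read_dicom_series: directory mixes multiple series: ",
         paste(sort(unique(uids)), collapse = ", "))
  first <- atts[[1L]]
  if (is.null(first$ImageOrientationPatient) ||
      is.null(first$ImagePositionPatient) || is.null(first$PixelSpacing))
    stop("read_dicom_series: missing spatial attributes ",
         "(ImagePositionPatient / ImageOrientationPatient / PixelSpacing)")
  iop <- first$ImageOrientationPatient
  xdir <- iop[1:3]; ydir <- iop[4:6]
  normal <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
              xdir[3] * ydir[1] - xdir[1] * ydir[3],
              xdir[1] * ydir[2] - xdir[2] * ydir[1])
  multiframe <- length(files) == 1L && !is.null(first$NumberOfFrames) &&
    first$NumberOfFrames > 1L
  if (multiframe) {
    a <- .decode_pixels(first, files[1L])
    if (length(dim(a)) == 4L && dim(a)[4] == 3L)
      stop("read_dicom_series: RGB multi-frame not supported")
    nsl <- dim(a)[3]
    dz <- if (!is.null(first$SpacingBetweenSlices)) first$SpacingBetweenSlices
          else if (!is.null(first$SliceThickness)) first$SliceThickness
          else stop("read_dicom_series: multi-frame file lacks slice spacing")
    ipp0 <- first$ImagePositionPatient
    data <- a
    slope <- if (is.null(first$RescaleSlope)) 1 else first$RescaleSlope
    inter <- if (is.null(first$RescaleIntercept)) 0 else first$RescaleIntercept
    data <- data * slope + inter
  } else {
    proj <- vapply(atts, function(a) {
      if (is.null(a$ImagePositionPatient))
        stop("read_dicom_series: slice without ImagePositionPatient")
      sum(a$ImagePositionPatient * normal)
    }, 0)
    ord <- order(proj)
    atts <- atts[ord]; files <- files[ord]; proj <- proj[ord]
    if (length(files) > 1L) {
      steps <- diff(proj)
      dz <- mean(steps)
      if (dz <= 0 || any(abs(steps - dz) > 0.01 * abs(dz)))
        stop("read_dicom_series: inconsistent slice spacing (tolerance 1%): ",
             paste(signif(steps, 5), collapse = ", "))
    } else {
      dz <- if (!is.null(first$SliceThickness)) first$SliceThickness else 1
    }
    slices <- lapply(seq_along(files), function(i) {
      a <- .decode_pixels(atts[[i]], files[i])
      slope <- if (is.null(atts[[i]]$RescaleSlope)) 1 else atts[[i]]$RescaleSlope
      inter <- if (is.null(atts[[i]]$RescaleIntercept)) 0
               else atts[[i]]$RescaleIntercept
      a * slope + inter
    })
    nd <- length(dim(slices[[1L]]))
    rgb <- nd == 4L && dim(slices[[1L]])[4] == 3L
    if (rgb) {
      d2 <- dim(slices[[1L]])[1:2]
      data <- array(0, c(d2, length(slices), 3))
      for (i in seq_along(slices)) data[, , i, ] <- slices[[i]][, , 1L, ]
    } else {
      d2 <- dim(slices[[1L]])[1:2]
      data <- array(0, c(d2, length(slices)))
      for (i in seq_along(slices)) data[, , i] <- slices[[i]][, , 1L]
    }
    ipp0 <- atts[[1L]]$ImagePositionPatient
  }
  # LPS -> RAS
  flip <- c(-1, -1, 1)
  spacing <- c(first$PixelSpacing[2], first$PixelSpacing[1], abs(dz))
  orientation <- cbind(flip * xdir, flip * ydir, flip * normal)
  origin <- flip * ipp0
  meta <- list(SeriesInstanceUID = first$SeriesInstanceUID,
               Modality = first$Modality,
               SeriesDescription = first$SeriesDescription,
               PatientID = first$PatientID)
  if (length(dim(data)) == 4L)
    rgb_volume(data, spacing, origin, orientation, meta)
  else
    volume(data, spacing, origin, orientation, meta)
}

## ---- writing ----

.pad_even <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2 == 1) c(raw, pad) else raw
}

.enc_str <- function(s, nul = FALSE) {
  .pad_even(charToRaw(s), if (nul) as.raw(0) else as.raw(0x20))
}

.enc_ds <- function(x) {
  s <- vapply(x, function(v) {
    out <- formatC(v, format = "g", digits = 10)
    if (nchar(out) > 16) out <- formatC(v, format = "g", digits = 8)
    out
  }, "")
  .enc_str(paste(s, collapse = "\\"))
}

.enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.enc_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.element <- function(group, elem, vr, payload) {
  payload <- if (length(payload) %% 2 == 1) c(payload, as.raw(0)) else payload
  head <- c(.enc_u16(group), .enc_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, as.raw(c(0, 0)), .enc_u32(length(payload)), payload)
  } else {
    if (length(payload) > 65534) stop("DICOM element too long for short VR")
    c(head, .enc_u16(length(payload)), payload)
  }
}

# deterministic UID derived from content (2.25.<decimal of md5 prefix>)
.content_uid <- function(...) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(list(...), NULL), tf)
  h <- unname(tools::md5sum(tf))
  paste0("2.25.", strtoi(substr(h, 1, 7), 16L), strtoi(substr(h, 8, 14), 16L),
         strtoi(substr(h, 15, 21), 16L))
}

# assemble and write one secondary-capture file
.write_sc_file <- function(file, sop_uid, study_uid, series_uid, instance,
                           ipp_lps, iop_lps, pixel_spacing, thickness,
                           rows, cols, pixel_payload, rgb, bits,
                           rescale = NULL, nframes = NULL,
                           series_desc = "rapid wash-out map",
                           patient_id = "ANON") {
  ds <- c(
    .element(0x0008, 0x0008, "CS", .enc_str("DERIVED\\SECONDARY")),
    .element(0x0008, 0x0016, "UI", .enc_str(SC_SOP_CLASS, nul = TRUE)),
    .element(0x0008, 0x0018, "UI", .enc_str(sop_uid, nul = TRUE)),
    .element(0x0008, 0x0060, "CS", .enc_str("OT")),
    .element(0x0008, 0x103E, "LO", .enc_str(series_desc)),
    .element(0x0010, 0x0010, "PN", .enc_str(patient_id)),
    .element(0x0010, 0x0020, "LO", .enc_str(patient_id)),
    .element(0x0018, 0x0050, "DS", .enc_ds(thickness)),
    .element(0x0018, 0x0088, "DS", .enc_ds(thickness)),
    .element(0x0020, 0x000D, "UI", .enc_str(study_uid, nul = TRUE)),
    .element(0x0020, 0x000E, "UI", .enc_str(series_uid, nul = TRUE)),
    .element(0x0020, 0x0011, "IS", .enc_str("1")),
    .element(0x0020, 0x0013, "IS", .enc_str(sprintf("%d", instance))),
    .element(0x0020, 0x0032, "DS", .enc_ds(ipp_lps)),
    .element(0x0020, 0x0037, "DS", .enc_ds(iop_lps)),
    .element(0x0028, 0x0002, "US", .enc_u16(if (rgb) 3L else 1L)))
  if (rgb)
    ds <- c(ds, .element(0x0028, 0x0004, "CS", .enc_str("RGB")),
            .element(0x0028, 0x0006, "US", .enc_u16(0L)))
  else
    ds <- c(ds, .element(0x0028, 0x0004, "CS", .enc_str("MONOCHROME2")))
  if (!is.null(nframes))
    ds <- c(ds, .element(0x0028, 0x0008, "IS",
                         .enc_str(sprintf("%d", nframes))))
  ds <- c(ds,
    .element(0x0028, 0x0010, "US", .enc_u16(rows)),
    .element(0x0028, 0x0011, "US", .enc_u16(cols)),
    .element(0x0028, 0x0030, "DS", .enc_ds(pixel_spacing)),
    .element(0x0028, 0x0100, "US", .enc_u16(bits)),
    .element(0x0028, 0x0101, "US", .enc_u16(bits)),
    .element(0x0028, 0x0102, "US", .enc_u16(bits - 1L)),
    .element(0x0028, 0x0103, "US", .enc_u16(0L)))
  if (!is.null(rescale))
    ds <- c(ds,
      .element(0x0028, 0x1052, "DS", .enc_ds(rescale[1])),
      .element(0x0028, 0x1053, "DS", .enc_ds(rescale[2])))
  ds <- c(ds, .element(0x7FE0, 0x0010, if (bits == 8) "OB" else "OW",
                       pixel_payload))
  meta_body <- c(
    .element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .element(0x0002, 0x0002, "UI", .enc_str(SC_SOP_CLASS, nul = TRUE)),
    .element(0x0002, 0x0003, "UI", .enc_str(sop_uid, nul = TRUE)),
    .element(0x0002, 0x0010, "UI", .enc_str(EXPLICIT_LE, nul = TRUE)),
    .element(0x0002, 0x0012, "UI",
             .enc_str("2.25.845394240566219", nul = TRUE)))
  meta <- c(.element(0x0002, 0x0000, "UL", .enc_u32(length(meta_body))),
            meta_body)
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(file)
}

# shared geometry for slice writers: returns LPS quantities per slice
.sc_geometry <- function(geom) {
  flip <- c(-1, -1, 1)
  iop_lps <- c(flip * geom$orientation[, 1], flip * geom$orientation[, 2])
  ipp <- function(k)
    flip * drop(voxel_to_world(geom, c(0, 0, k - 1)))
  list(iop = iop_lps, ipp = ipp,
       pixel_spacing = c(geom$spacing[2], geom$spacing[1]),
       thickness = geom$spacing[3])
}

#' Write a grayscale volume as a secondary-capture DICOM series
#'
#' One file per slice; spatial attributes (position, orientation, pixel
#' spacing, slice spacing) are taken from the volume's geometry so PACS
#' viewers align the series with its source. Integer data in `[0, 255]` is
#' stored as 8-bit; anything else as 16-bit with a rescale slope/intercept
#' chosen to cover the data range.
#'
#' @param vol a [volume()].
#' @param directory output directory (created if missing).
#' @param series_desc series description string.
#' @return character vector of written file paths (one per slice).
#' @export
write_gray_dicom <- function(vol, directory,
                             series_desc = "rapid wash-out gray") {
  stopifnot(is_volume(vol))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$data)
  g <- .sc_geometry(vol)
  vals <- vol$data
  eight_bit <- all(vals >= 0 & vals <= 255) &&
    max(abs(vals - round(vals))) == 0
  if (eight_bit) {
    rescale <- NULL; bits <- 8L
    # column-major flatten of [col, row] is exactly DICOM's row-major pixel
    # order (column index fastest within each row)
    enc <- function(m) as.raw(as.integer(m))
  } else {
    lo <- min(vals); hi <- max(vals)
    slope <- if (hi > lo) (hi - lo) / 65535 else 1
    rescale <- c(lo, slope); bits <- 16L
    enc <- function(m) {
      stored <- as.integer(round((as.vector(m) - lo) / slope))
      writeBin(ifelse(stored > 32767L, stored - 65536L, stored), raw(),
               size = 2, endian = "little")
    }
  }
  study_uid <- .content_uid("study", vol$spacing, d)
  series_uid <- .content_uid("gray", vals, vol$origin)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    paths[k] <- file.path(directory, sprintf("slice_%04d.dcm", k))
    .write_sc_file(paths[k],
                   sop_uid = .content_uid(series_uid, k),
                   study_uid = study_uid, series_uid = series_uid,
                   instance = k, ipp_lps = g$ipp(k), iop_lps = g$iop,
                   pixel_spacing = g$pixel_spacing, thickness = g$thickness,
                   rows = d[2], cols = d[1],
                   pixel_payload = enc(vol$data[, , k]),
                   rgb = FALSE, bits = bits, rescale = rescale,
                   series_desc = series_desc)
  }
  paths
}

#' Write an RGB volume as a secondary-capture DICOM series
#'
#' Writes the two-color wash-out rendering as one 8-bit-per-channel RGB
#' secondary-capture file per slice. The spatial attributes are copied from
#' `reference` (which must share the grid) so the color series overlays the
#' source anatomy in a PACS viewer.
#'
#' @param rgb an [rgb_volume()].
#' @param reference a [volume()] on the same grid supplying geometry.
#' @param directory output directory (created if missing).
#' @param series_desc series description string.
#' @return character vector of written file paths.
#' @export
write_rgb_dicom <- function(rgb, reference, directory,
                            series_desc = "rapid wash-out map RGB") {
  stopifnot(is_rgb_volume(rgb), is_volume(reference))
  if (!identical(dim(rgb$data)[1:3], dim(reference$data)) ||
      max(abs(rgb$spacing - reference$spacing)) > 1e-4)
    stop("write_rgb_dicom: rgb and reference grids do not match")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(reference$data)
  g <- .sc_geometry(reference)
  study_uid <- .content_uid("study", reference$spacing, d)
  series_uid <- .content_uid("rgb", rgb$data, reference$origin)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    # interleaved R,G,B per pixel, rows of the image in row-major order
    sl <- rgb$data[, , k, , drop = FALSE]      # cols x rows x 1 x 3
    inter <- aperm(array(sl, c(d[1], d[2], 3)), c(3, 1, 2))
    paths[k] <- file.path(directory, sprintf("slice_%04d.dcm", k))
    .write_sc_file(paths[k],
                   sop_uid = .content_uid(series_uid, k),
                   study_uid = study_uid, series_uid = series_uid,
                   instance = k, ipp_lps = g$ipp(k), iop_lps = g$iop,
                   pixel_spacing = g$pixel_spacing, thickness = g$thickness,
                   rows = d[2], cols = d[1],
                   pixel_payload = as.raw(as.integer(inter)),
                   rgb = TRUE, bits = 8L, series_desc = series_desc)
  }
  paths
}
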