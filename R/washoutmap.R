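#' Subtract the registered late series from the early series
#'
#' Voxelwise early minus late on a shared grid. Positive values mean the
#' early acquisition was brighter (contrast wash-out, rendered red
#' downstream); negative values mean late accumulation (wash-in, green).
#' The valid mask excludes fill/`NA` voxels of either input and, when
#' given, restricts to the foreground.
#'
#' @param early,late_registered [volume()]s on the same grid (register
#'   first; both mean-normalized).
#' @param mask optional logical foreground mask further restricting
#'   validity.
#' @return an object of class `washout_difference`: fields `data` (signed
#'   [volume()], `NA` outside the valid mask kept as values), `valid_mask`
#'   (logical array) and `clip_range` (`NULL` until [encode_map()] fixes it).
#' @export
subtract_series <- function(early, late_registered, mask = NULL) {
  stopifnot(is_volume(early), is_volume(late_registered))
  if (!same_grid(early, late_registered))
    stop("subtract_series: volumes are not on the same grid; register first")
  d <- early$data - late_registered$data
  valid <- !is.na(early$data) & !is.na(late_registered$data)
  if (!is.null(mask)) valid <- valid & mask
  structure(list(data = with_data(early, d), valid_mask = valid,
                 clip_range = NULL),
            class = "washout_difference")
}

#' @export
print.washout_difference <- function(x, ...) {
  v <- x$data$data[x$valid_mask]
  cat(sprintf("<washout_difference> %s valid voxels, range [%s, %s]\n",
              sum(x$valid_mask), signif(min(v), 4), signif(max(v), 4)))
  invisible(x)
}

#' Encode a difference volume as 8-bit grayscale and two-color RGB maps
#'
#' The display clip range `C` is half the observed peak-to-peak value range
#' over valid voxels (the value range halved), or a symmetric percentile
#' range for robustness. Values are clipped to `[-C, +C]` and mapped to
#' 8 bits so that a zero difference lands exactly at 127 of 255, `-C` at 0
#' and `+C` at 255 (`g = floor(127.5 * (1 + d/C))`). The RGB rendering
#' holds all channels at a neutral level for `d = 0` and raises the red
#' channel linearly to 255 at `+C` (wash-out) or the green channel at `-C`
#' (wash-in). The neutral level is mid-gray 127 by default, or a dimmed
#' grayscale anatomy underlay when `underlay` is supplied.
#'
#' @param diff a `washout_difference` from [subtract_series()].
#' @param clip `"halfrange"` (default) or `"percentile"`.
#' @param percentiles lower/upper quantiles used when `clip = "percentile"`.
#' @param underlay optional [volume()] on the same grid; its intensities
#'   are compressed to `[0, 127]` and used as the neutral RGB level so
#'   anatomy remains visible beneath the color coding.
#' @return an object of class `washout_map`: fields `difference` (with
#'   `clip_range` set), `gray` ([volume()] of 0-255 codes, invalid voxels
#'   0), `rgb` ([rgb_volume()]) and `provenance` (settings list).
#' @export
encode_map <- function(diff, clip = c("halfrange", "percentile"),
                       percentiles = c(0.005, 0.995), underlay = NULL) {
  clip <- match.arg(clip)
  stopifnot(inherits(diff, "washout_difference"))
  v <- diff$data$data[diff$valid_mask]
  uniform <- length(v) == 0L || max(v) == min(v)
  if (uniform) {
    if (!length(v) || all(v == 0)) {
      warning("encode_map: uniform zero difference; output is flat 127")
      C <- 1
    } else C <- max(abs(v))
  } else if (clip == "halfrange") {
    C <- (max(v) - min(v)) / 2
  } else {
    q <- stats::quantile(v, percentiles, names = FALSE)
    C <- max((q[2] - q[1]) / 2, .Machine$double.eps)
  }
  d <- diff$data$data
  d[!diff$valid_mask] <- 0
  dc <- pmin(pmax(d, -C), C)           # array first: keeps dim()
  gray <- pmin(floor(127.5 * (1 + dc / C)), 255)
  gray[!diff$valid_mask] <- 0
  dims <- dim(d)
  neutral <- if (is.null(underlay)) {
    array(127L, dims)
  } else {
    stopifnot(is_volume(underlay), identical(dim(underlay$data), dims))
    u <- underlay$data
    u <- u - min(u, na.rm = TRUE)
    mx <- max(u, na.rm = TRUE)
    if (mx > 0) u <- u / mx
    u[is.na(u)] <- 0
    array(as.integer(floor(u * 127)), dims)
  }
  mag <- pmin(floor(127.5 * (1 + abs(dc) / C)), 255)   # 127..255
  lift <- (mag - 127) / 128                            # 0..1
  up <- neutral + floor((255 - neutral) * lift)
  rgbd <- array(0L, c(dims, 3))
  rgbd[, , , 1] <- ifelse(d > 0, up, neutral)
  rgbd[, , , 2] <- ifelse(d < 0, up, neutral)
  rgbd[, , , 3] <- neutral
  rgbd[is.na(rgbd)] <- 0L
  diff$clip_range <- C
  structure(list(
    difference = diff,
    gray = with_data(diff$data, gray),
    rgb = rgb_volume(rgbd, diff$data$spacing, diff$data$origin,
                     diff$data$orientation),
    provenance = list(clip = clip, clip_range = C,
                      percentiles = if (clip == "percentile") percentiles,
                      underlay = !is.null(underlay), uniform = uniform)),
    class = "washout_map")
}

#' @export
print.washout_map <- function(x, ...) {
  cat(sprintf("<washout_map> clip range +/- %s, %s clip policy\n",
              signif(x$difference$clip_range, 5), x$provenance$clip))
  invisible(x)
}

#' Decode an encoded map back to difference values
#'
#' Inverse of the grayscale encoding: `d = (g - 127) * C / 127.5`, clamped
#' to `[-C, +C]`. For any input difference `d`,
#' `|decode(encode(d)) - clip(d)| <= C / 255` at every valid voxel.
#'
#' @param map a `washout_map` from [encode_map()].
#' @return a `washout_difference` whose data are the decoded values
#'   (0 outside the valid mask).
#' @export
decode_map <- function(map) {
  stopifnot(inherits(map, "washout_map"))
  C <- map$difference$clip_range
  if (is.null(C)) stop("decode_map: map has no stored clip_range")
  g <- map$gray$data
  d <- pmin(pmax((g - 127) * C / 127.5, -C), C)
  d[!map$difference$valid_mask] <- 0
  structure(list(data = with_data(map$gray, d),
                 valid_mask = map$difference$valid_mask, clip_range = C),
            class = "washout_difference")
}
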