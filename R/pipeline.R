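#' Build a pipeline run configuration
#'
#' All settings default to their anchored values: bias-field shrink factor
#' 3, registration by normalized mutual information, display clip at half
#' the value range with midpoint 127, segmentation threshold 3 sigma, rCBV
#' threshold 1.2, minimum perfusion cross-section 0.25 cm^2. The full
#' configuration is serialized verbatim into the output manifest, from
#' which a run can be re-executed.
#'
#' @param early,late input paths (DICOM directory or NIfTI file) or
#'   [volume()]s.
#' @param rcbv optional co-registered rCBV map (path or [volume()]).
#' @param native optional pre-contrast series for the
#'   enhancement-screening advisory.
#' @param roi optional logical restriction mask for volumetry.
#' @param output_dir output directory.
#' @param bias_shrink,bias_enabled bias-correction settings.
#' @param registration_metric `"nmi"`, `"cr"` or `"ncc"`.
#' @param clip `"halfrange"` or `"percentile"` display-range policy.
#' @param segmentation_k threshold multiplier on the noise scale.
#' @param min_component_mm3 minimum compartment component volume.
#' @param rcbv_threshold,min_area_cm2 perfusion volumetry settings.
#' @param edge_erosion_voxels foreground erosion (in voxels) applied
#'   before subtraction statistics, removing the partial-volume rim at the
#'   head boundary where resampled differences are meaningless.
#' @param rgb_underlay use the anatomy underlay in the RGB rendering.
#' @param seed integer seed recorded and set before the run.
#' @return a `washout_config` list.
#' @export
run_config <- function(early, late, rcbv = NULL, native = NULL, roi = NULL,
                       output_dir = tempfile("washout_case_"),
                       bias_shrink = 3L, bias_enabled = TRUE,
                       registration_metric = "nmi",
                       clip = "halfrange", segmentation_k = 3,
                       min_component_mm3 = 50,
                       rcbv_threshold = 1.2, min_area_cm2 = 0.25,
                       edge_erosion_voxels = 2L,
                       rgb_underlay = FALSE, seed = 1L) {
  structure(list(early = early, late = late, rcbv = rcbv, native = native,
                 roi = roi, output_dir = output_dir,
                 bias_shrink = as.integer(bias_shrink),
                 bias_enabled = isTRUE(bias_enabled),
                 registration_metric = registration_metric, clip = clip,
                 segmentation_k = segmentation_k,
                 min_component_mm3 = min_component_mm3,
                 rcbv_threshold = rcbv_threshold,
                 min_area_cm2 = min_area_cm2,
                 edge_erosion_voxels = as.integer(edge_erosion_voxels),
                 rgb_underlay = isTRUE(rgb_underlay),
                 seed = as.integer(seed)),
            class = "washout_config")
}

.load_input <- function(x, what) {
  if (is_volume(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (dir.exists(x)) return(read_dicom_series(x))
    if (file.exists(x)) return(read_nifti(x))
    stop("input stage [", what, "]: path not found: ", x)
  }
  stop("input stage [", what, "]: expected a volume, NIfTI file or DICOM directory")
}

# md5 of the raw bytes of numeric arrays: the run's reproducibility checksum
.numeric_checksum <- function(...) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  for (x in list(...)) writeBin(as.vector(as.numeric(x)), con)
  close(con)
  unname(tools::md5sum(tf))
}

#' Screen the early series for contrast enhancement
#'
#' Advisory mirror of the clinical shortening rule: when a pre-contrast
#' (native) series is available, both series are mean-normalized and the
#' focal enhancement score — the mean of the top 1% of early-minus-native
#' differences over the foreground, relative to the common mean — is
#' compared against `threshold`. Below it, the recommendation is to skip
#' the late acquisition and wash-out mapping. Never aborts a run by
#' itself.
#'
#' @param early post-contrast early [volume()].
#' @param native optional pre-contrast [volume()] on a comparable grid.
#' @param threshold relative enhancement score below which skipping is
#'   recommended.
#' @return list: `proceed` (logical), `reason`, `score` (`NA` when not
#'   evaluated).
#' @export
shortened_protocol_check <- function(early, native = NULL, threshold = 0.05) {
  if (is.null(native))
    return(list(proceed = TRUE, reason = "no native series; enhancement not evaluated",
                score = NA_real_))
  stopifnot(is_volume(early), is_volume(native))
  nm <- normalize_means(early, native)
  mask <- foreground_mask(early)
  d <- nm$early$data[mask] - nm$late$data[mask]
  top <- d[d >= stats::quantile(d, 0.99, names = FALSE)]
  score <- mean(top) / nm$target
  if (score < threshold)
    list(proceed = FALSE,
         reason = sprintf("no substantial contrast enhancement (score %.4f < %.2f); protocol shortening recommended",
                          score, threshold), score = score)
  else
    list(proceed = TRUE,
         reason = sprintf("contrast enhancement detected (score %.4f)", score),
         score = score)
}

#' Run the full wash-out mapping pipeline on one case
#'
#' Stages, in order: read inputs, bias-field correction per series, joint
#' mean normalization, rigid registration of the late onto the early
#' series, subtraction (early minus late), 8-bit grayscale and two-color
#' RGB encoding, compartment segmentation and volumetry, optional
#' rCBV-threshold perfusion volumetry, and report writing. Outputs: the
#' signed difference and encoded gray map as NIfTI, gray and RGB DICOM
#' series, compartment masks as NIfTI, a per-lesion CSV, the transform
#' sidecar and a JSON provenance manifest holding every setting, scale
#' factor, the transform, the clip range, stage timings and a checksum of
#' all numeric outputs. Any stage failure aborts with a stage-labelled
#' error.
#'
#' @param config a [run_config()].
#' @return list: `volumetry`, `perfusion` (or `NULL`), `map`,
#'   `registration`, `screening`, `manifest` (the manifest list, also
#'   written as JSON), `output_dir`.
#' @export
run_case <- function(config) {
  stopifnot(inherits(config, "washout_config"))
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    out
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  early <- stage("read-early", .load_input(config$early, "early"))
  late <- stage("read-late", .load_input(config$late, "late"))
  native <- if (!is.null(config$native))
    stage("read-native", .load_input(config$native, "native"))
  screening <- stage("enhancement-screen",
                     shortened_protocol_check(early, native))

  if (config$bias_enabled) {
    bc_early <- stage("bias-early", correct_bias(early, config$bias_shrink))
    bc_late <- stage("bias-late", correct_bias(late, config$bias_shrink))
    early_c <- bc_early$corrected; late_c <- bc_late$corrected
    bias_flags <- c(bc_early$flag, bc_late$flag)
  } else {
    early_c <- early; late_c <- late
    bias_flags <- c("disabled", "disabled")
  }

  norm <- stage("normalize", normalize_means(early_c, late_c))
  reg <- stage("register",
               estimate_rigid(norm$early, norm$late,
                              metric = config$registration_metric))
  late_res <- stage("resample",
                    apply_transform(norm$late, reg$transform, norm$early))
  fg <- stage("foreground",
              erode_mask(foreground_mask(norm$early),
                         config$edge_erosion_voxels))
  diff <- stage("subtract", subtract_series(norm$early, late_res, mask = fg))
  map <- stage("encode",
               encode_map(diff, clip = config$clip,
                          underlay = if (config$rgb_underlay) norm$early))
  masks <- stage("segment",
                 segment_compartments(diff, k = config$segmentation_k,
                                      min_component_mm3 = config$min_component_mm3,
                                      roi = config$roi))
  volumetry <- stage("measure", measure_compartments(masks))
  perfusion <- if (!is.null(config$rcbv)) {
    rcbv <- stage("read-rcbv", .load_input(config$rcbv, "rcbv"))
    stage("perfusion", segment_perfusion(rcbv, config$rcbv_threshold,
                                         config$min_area_cm2))
  }

  out <- config$output_dir
  stage("write-outputs", {
    write_nifti(diff$data, file.path(out, "difference.nii"))
    write_nifti(map$gray, file.path(out, "washout_gray.nii"))
    write_gray_dicom(map$gray, file.path(out, "dicom_gray"))
    write_rgb_dicom(map$rgb, map$gray, file.path(out, "dicom_rgb"))
    write_mask_nifti(masks$washout_mask, diff$data,
                     file.path(out, "washout_mask.nii"))
    write_mask_nifti(masks$washin_mask, diff$data,
                     file.path(out, "washin_mask.nii"))
    if (!is.null(perfusion))
      write_mask_nifti(perfusion$mask, diff$data,
                       file.path(out, "perfusion_mask.nii"))
    write_transform(reg$transform, file.path(out, "transform.txt"))
    lesions <- volumetry$lesions
    utils::write.csv(lesions, file.path(out, "lesions.csv"),
                     row.names = FALSE)
    TRUE
  })

  checksum <- .numeric_checksum(
    diff$data$data[diff$valid_mask], map$gray$data, map$rgb$data,
    masks$washout_mask, masks$washin_mask,
    volumetry$washout_mm3, volumetry$washin_mm3,
    if (volumetry$ratio_defined) volumetry$washout_ratio else -1,
    transform_matrix(reg$transform),
    if (!is.null(perfusion)) perfusion$volume_mm3 else -1)

  manifest <- list(
    software = "rapidwashout",
    version = as.character(utils::packageVersion("rapidwashout")),
    config = config[setdiff(names(config),
                            c("early", "late", "rcbv", "native", "roi"))],
    inputs = list(
      early = if (is.character(config$early)) config$early else "<in-memory volume>",
      late = if (is.character(config$late)) config$late else "<in-memory volume>",
      rcbv = if (is.character(config$rcbv)) config$rcbv else
        if (is.null(config$rcbv)) NULL else "<in-memory volume>"),
    screening = screening[c("proceed", "reason")],
    bias_flags = bias_flags,
    normalization = list(scale = unname(norm$scale), target = norm$target),
    registration = list(converged = reg$converged, cost = reg$cost,
                        cost_identity = reg$cost_identity,
                        metric = config$registration_metric,
                        matrix = transform_matrix(reg$transform)),
    encoding = map$provenance,
    volumetry = list(threshold = masks$threshold,
                     washout_mm3 = volumetry$washout_mm3,
                     washin_mm3 = volumetry$washin_mm3,
                     washout_ratio = volumetry$washout_ratio,
                     ratio_defined = volumetry$ratio_defined,
                     lesion_count = volumetry$lesion_count),
    perfusion = if (!is.null(perfusion))
      perfusion[c("volume_mm3", "max_rcbv", "threshold", "min_area_cm2")],
    timings = timings,
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3),
    checksum = checksum)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(volumetry = volumetry, perfusion = perfusion, map = map,
                 registration = reg, screening = screening,
                 manifest = manifest, output_dir = out))
}
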