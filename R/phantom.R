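#' Tissue-class contrast-enhancement kinetics
#'
#' Each tissue class carries a baseline T1 intensity and an enhancement
#' curve `baseline + A * f(t)` with `f(0) = 0`:
#' * `"gamma"` — gamma-variate-like bolus curve
#'   `f(t) = (t/tp)^shape * exp(shape * (1 - t/tp))`, peaking at 1 when
#'   `t = tp`; models fast-enhancing, fast-clearing tissue (enhancing
#'   tumor, vessels) whose signal declines between an early (~5 min) and a
#'   late (~20 min) acquisition.
#' * `"satexp"` — saturating exponential `f(t) = 1 - exp(-t / tau)`;
#'   models slow monotone accumulation in scar/necrosis that is still
#'   rising at the late scan (wash-in).
#' * `"flat"` — `f(t) = 0`; non-enhancing tissue.
#'
#' @param class class name (e.g. `"normal"`, `"vessel"`,
#'   `"enhancing_tumor"`, `"necrosis_scar"`, `"edema"`).
#' @param baseline non-negative baseline intensity.
#' @param amplitude enhancement amplitude `A` (intensity units).
#' @param family `"gamma"`, `"satexp"` or `"flat"`.
#' @param tp time-to-peak (min) for `"gamma"`.
#' @param shape gamma-variate shape (steepness of wash-out).
#' @param tau uptake time constant (min) for `"satexp"`.
#' @return an object of class `washout_kinetics`.
#' @export
tissue_kinetics <- function(class, baseline, amplitude = 0,
                            family = c("flat", "gamma", "satexp"),
                            tp = 5, shape = 1.5, tau = 15) {
  family <- match.arg(family)
  stopifnot(baseline >= 0, amplitude >= 0, tp > 0, tau > 0, shape > 0)
  structure(list(class = class, baseline = baseline, amplitude = amplitude,
                 family = family, tp = tp, shape = shape, tau = tau),
            class = "washout_kinetics")
}

#' Evaluate an enhancement curve
#' @param tk a [tissue_kinetics()].
#' @param t time after contrast injection, minutes (vectorized, `t >= 0`).
#' @return intensity at `t` (baseline exactly at `t = 0`).
#' @export
enhancement <- function(tk, t) {
  stopifnot(inherits(tk, "washout_kinetics"), all(t >= 0))
  f <- switch(tk$family,
              flat = rep(0, length(t)),
              gamma = (t / tk$tp)^tk$shape * exp(tk$shape * (1 - t / tk$tp)),
              satexp = 1 - exp(-t / tk$tau))
  tk$baseline + tk$amplitude * f
}

#' Default tissue kinetics of the digital phantom
#'
#' Anchors: fast-peaking classes peak near 5 min (glioblastoma-like
#' maximum enhancement at about 3-8 min), so they are brighter at the
#' early (~5 min) than the late (~20 min) acquisition; scar/necrosis
#' accumulates slowly (time constant 15 min) and is brighter late.
#' Baselines approximate relative T1 tissue intensities.
#'
#' @return named list of [tissue_kinetics()] (background, normal, edema,
#'   vessel, enhancing_tumor, necrosis_scar).
#' @export
default_kinetics <- function() {
  list(
    background = tissue_kinetics("background", 0),
    normal = tissue_kinetics("normal", 100),
    edema = tissue_kinetics("edema", 85),
    vessel = tissue_kinetics("vessel", 90, 80, "gamma", tp = 3, shape = 2),
    enhancing_tumor = tissue_kinetics("enhancing_tumor", 80, 60, "gamma",
                                      tp = 5, shape = 1.5),
    necrosis_scar = tissue_kinetics("necrosis_scar", 70, 70, "satexp",
                                    tau = 12))
}

#' Default phantom layout
#'
#' A head ellipsoid containing parametric lesions: a spherical enhancing
#' tumor, a spherical scar/necrosis region, a cylindrical vessel, and
#' optionally a ring (shell) lesion mimicking the rim pattern of radiation
#' necrosis. All positions/radii in world mm; analytic shapes give exact
#' voxelized truth masks. Lesion centers deliberately avoid grid-aligned
#' positions: a sphere centred exactly on a voxel makes its voxelized
#' volume a worst case of the discretization (about +9% for 1 cm^3 at
#' 2 mm spacing), which no real lesion exhibits.
#'
#' @param tumor_volume_cm3 target tumor sphere volume.
#' @param with_ring add a ring-shaped wash-out shell.
#' @return list describing the layout (consumed by [generate_phantom()]).
#' @export
default_layout <- function(tumor_volume_cm3 = 2, with_ring = FALSE) {
  r_t <- (3 * tumor_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  list(
    head = list(center = c(0, 0, 0), radii = c(70, 85, 60)),
    lesions = c(list(
      list(class = "enhancing_tumor", shape = "sphere",
           center = c(25.7, 10.3, 8.9), radius = r_t),
      list(class = "necrosis_scar", shape = "sphere",
           center = c(-28.4, -12.3, 0.6), radius = 11),
      list(class = "vessel", shape = "cylinder",
           center = c(0, -40, 0), radius = 2.5, axis = 3, half_length = 35)),
      if (with_ring) list(list(class = "enhancing_tumor", shape = "shell",
                               center = c(20, -35, -15), radius = 12,
                               thickness = 3))))
}

.shape_mask <- function(shape, xg, yg, zg) {
  cx <- shape$center
  if (shape$shape == "sphere") {
    (xg - cx[1])^2 + (yg - cx[2])^2 + (zg - cx[3])^2 <= shape$radius^2
  } else if (shape$shape == "shell") {
    r2 <- (xg - cx[1])^2 + (yg - cx[2])^2 + (zg - cx[3])^2
    r2 <= shape$radius^2 & r2 >= (shape$radius - shape$thickness)^2
  } else if (shape$shape == "cylinder") {
    ax <- shape$axis
    co <- list(xg, yg, zg)
    perp <- setdiff(1:3, ax)
    (co[[perp[1]]] - cx[perp[1]])^2 + (co[[perp[2]]] - cx[perp[2]])^2 <=
      shape$radius^2 & abs(co[[ax]] - cx[ax]) <= shape$half_length
  } else stop("unknown shape ", shape$shape)
}

# smooth multiplicative bias field: low-order polynomial with seeded
# coefficients, scaled so its multiplicative range is about 1 +/- amplitude
.random_bias_field <- function(dims, amplitude) {
  if (amplitude <= 0) return(array(1, dims))
  u <- lapply(dims, function(n) seq(-1, 1, length.out = n))
  cf <- stats::runif(9, -1, 1)
  xg <- array(rep(u[[1]], times = dims[2] * dims[3]), dims)
  yg <- array(rep(rep(u[[2]], each = dims[1]), times = dims[3]), dims)
  zg <- array(rep(u[[3]], each = dims[1] * dims[2]), dims)
  f <- cf[1] * xg + cf[2] * yg + cf[3] * zg + cf[4] * xg * yg +
    cf[5] * xg * zg + cf[6] * yg * zg + cf[7] * xg^2 + cf[8] * yg^2 +
    cf[9] * zg^2
  rng <- max(f) - min(f)
  if (rng == 0) return(array(1, dims))
  1 + amplitude * (2 * (f - min(f)) / rng - 1)
}

#' Generate a paired early/late phantom case with ground truth
#'
#' Renders the analytic scene twice: the early volume samples every tissue
#' class's enhancement curve at `t_early`, the late volume at `t_late` on a
#' grid rigidly moved by `transform` (the scene is evaluated analytically
#' at transformed coordinates, so the misalignment carries no interpolation
#' error). Independent smooth multiplicative bias fields are applied per
#' series, then Gaussian (or Rician) noise at the stated SNR (SNR = mean
#' head intensity of the clean early volume / noise sigma). A synthetic
#' rCBV map co-registered to the early grid is elevated in vessel and
#' enhancing-tumor tissue and at or below 1 elsewhere. Fully reproducible
#' for a fixed seed.
#'
#' @param layout from [default_layout()].
#' @param kinetics named list of [tissue_kinetics()] covering every class
#'   in the layout plus `background` and `normal`.
#' @param t_early,t_late acquisition times in minutes after contrast
#'   (defaults 5 and 20: first post-contrast scan about 5 min after
#'   injection, second about 15 min later).
#' @param transform true rigid misalignment between the series (a
#'   [rigid_transform()]; identity by default). It maps early-grid world
#'   points to the late scene, i.e. it is the transform registration
#'   should recover.
#' @param bias_amplitude multiplicative bias range (0.1 = +/-10%).
#' @param snr signal-to-noise ratio; `Inf` for noise-free.
#' @param noise `"gaussian"` or `"rician"`.
#' @param texture_amplitude scale factor on the parenchymal texture of
#'   normal brain (1 = default modulation, 0 = uniform tissue).
#' @param dims,spacing grid size and voxel spacing (mm).
#' @param rcbv_values named vector of rCBV per class (ratio units).
#' @param seed integer seed; the generator is bit-reproducible given it.
#' @return list: `early`, `late`, `rcbv` ([volume()]s) and `truth` (class
#'   label volume, logical `washout_mask` / `washin_mask` on the early
#'   grid, applied `transform`, both bias fields, kinetics, times, noise
#'   sigma, seed).
#' @export
generate_phantom <- function(layout = default_layout(),
                             kinetics = default_kinetics(),
                             t_early = 5, t_late = 20,
                             transform = rigid_transform(),
                             bias_amplitude = 0.1, snr = 20,
                             noise = c("gaussian", "rician"),
                             texture_amplitude = 1,
                             dims = c(96L, 96L, 72L), spacing = c(2, 2, 2),
                             rcbv_values = c(background = 0, normal = 0.8,
                                             edema = 0.9, vessel = 2.5,
                                             enhancing_tumor = 2.0,
                                             necrosis_scar = 0.6),
                             seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(snr > 0)
  set.seed(as.integer(seed))
  origin <- -(dims - 1) / 2 * spacing
  geom <- volume(array(0, dims), spacing, origin)
  # world coordinate grids on the early grid
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  xg <- array(rep(xs, times = dims[2] * dims[3]), dims)
  yg <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  zg <- array(rep(zs, each = dims[1] * dims[2]), dims)

  classes <- c("background", "normal",
               vapply(layout$lesions, `[[`, "", "class"))
  classes <- unique(classes)
  if (!all(classes %in% names(kinetics)))
    stop("generate_phantom: kinetics missing for class(es) ",
         paste(setdiff(classes, names(kinetics)), collapse = ", "))

  label_scene <- function(x, y, z) {
    head <- (x - layout$head$center[1])^2 / layout$head$radii[1]^2 +
      (y - layout$head$center[2])^2 / layout$head$radii[2]^2 +
      (z - layout$head$center[3])^2 / layout$head$radii[3]^2 <= 1
    lab <- array(ifelse(head, "normal", "background"), dim(x))
    for (les in layout$lesions) {
      m <- .shape_mask(les, x, y, z)
      if (any(m & !head) || !any(m))
        stop("generate_phantom: lesion '", les$class,
             "' lies outside the head (or outside the field of view)")
      lab[m] <- les$class
    }
    lab
  }

  # smooth parenchymal "texture" (gray/white-like modulation) anchored to
  # the scene in world coordinates, so it moves with the head; it gives
  # same-modality registration the internal structure a real brain has
  texture <- function(x, y, z)
    1 + texture_amplitude *
      (0.10 * (sin(x / 6.5) + sin(y / 8) + sin(z / 5.5)) / 3 +
         0.06 * sin(x / 15 + y / 11 - z / 13))

  render <- function(lab, t, x, y, z) {
    out <- array(0, dim(lab))
    for (cl in unique(as.vector(lab)))
      out[lab == cl] <- enhancement(kinetics[[cl]], t)
    nm <- lab == "normal"
    out[nm] <- out[nm] * texture(x[nm], y[nm], z[nm])
    out
  }

  lab_early <- label_scene(xg, yg, zg)
  early_clean <- render(lab_early, t_early, xg, yg, zg)
  # late series: the scene is moved by `transform`, so the late grid sees
  # the scene at inverse-transformed coordinates; registering late to early
  # then recovers `transform` itself
  pts <- transform_points(invert_transform(transform),
                          cbind(as.vector(xg), as.vector(yg), as.vector(zg)))
  xl <- array(pts[, 1], dims); yl <- array(pts[, 2], dims)
  zl <- array(pts[, 3], dims)
  lab_late <- label_scene(xl, yl, zl)
  late_clean <- render(lab_late, t_late, xl, yl, zl)

  bias_early <- .random_bias_field(dims, bias_amplitude)
  bias_late <- .random_bias_field(dims, bias_amplitude)
  sig <- mean(early_clean[lab_early != "background"])
  sigma <- if (is.finite(snr)) sig / snr else 0
  add_noise <- function(x) {
    if (sigma == 0) return(x)
    if (noise == "gaussian") x + stats::rnorm(length(x), 0, sigma)
    else sqrt((x + stats::rnorm(length(x), 0, sigma))^2 +
                stats::rnorm(length(x), 0, sigma)^2)
  }
  early <- with_data(geom, array(add_noise(early_clean * bias_early), dims))
  late <- with_data(geom, array(add_noise(late_clean * bias_late), dims))

  # truth compartments from the kinetics sign at the two times, early grid
  washout_classes <- Filter(function(cl)
    enhancement(kinetics[[cl]], t_early) > enhancement(kinetics[[cl]], t_late),
    classes)
  washin_classes <- Filter(function(cl)
    enhancement(kinetics[[cl]], t_late) > enhancement(kinetics[[cl]], t_early),
    classes)
  rcbv_data <- array(0, dims)
  for (cl in classes) {
    v <- if (cl %in% names(rcbv_values)) rcbv_values[[cl]] else 1
    rcbv_data[lab_early == cl] <- v
  }
  list(early = early, late = late,
       rcbv = with_data(geom, rcbv_data),
       truth = list(labels = lab_early,
                    washout_mask = array(lab_early %in% washout_classes, dims),
                    washin_mask = array(lab_early %in% washin_classes, dims),
                    transform = transform,
                    bias_early = bias_early, bias_late = bias_late,
                    kinetics = kinetics, t_early = t_early, t_late = t_late,
                    noise_sigma = sigma, noise = noise, seed = seed,
                    spacing = spacing))
}
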