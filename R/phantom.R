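#' Reference tissue sodium concentrations
#'
#' Mean and standard deviation of total sodium concentration (mM) per tissue
#' compartment, as measured in glioma patients at 7 T: normal-appearing white
#' matter (nawm), peritumoral edema, Gadolinium-contrast-enhancing tumor
#' (gdce), and central necrosis. These are the default ground-truth settings
#' of the synthetic phantom.
#'
#' @return A tibble with columns `region`, `mean_mM`, `sd_mM`.
#' @export
sodium_reference_values <- function() {
  tibble::tibble(
    region  = c("nawm", "edema", "gdce", "necrosis"),
    mean_mM = c(37.84, 54.69, 61.72, 81.88),
    sd_mM   = c(5.87, 10.64, 12.95, 17.53)
  )
}

#' Phantom specification
#'
#' Describes a compartmental brain phantom: a brain ellipsoid of nawm
#' containing nested tumor ellipsoids (necrosis core inside a gdce rim inside
#' an edema shell), plus two cylindrical NaCl reference vials outside the
#' brain. All geometry is in world millimetres; the grid origin is the corner
#' of voxel (1,1,1) and voxel centres sit at `(i - 0.5) * voxel_mm`.
#'
#' @param grid_shape Voxels per axis (length 1 or 3); default 64.
#' @param voxel_mm Isotropic voxel size in mm; default 3.
#' @param concentrations Named numeric vector of compartment truths in mM
#'   (names `nawm`, `edema`, `gdce`, `necrosis`); defaults from
#'   [sodium_reference_values()].
#' @param vial_percents NaCl content of the low/high reference vials, % w/v.
#' @param with_gdce,with_necrosis Presence flags for the inner compartments.
#' @param brain_center,brain_semiaxes mm; the nawm ellipsoid.
#' @param tumor_center mm; shared centre of the nested tumor ellipsoids.
#' @param edema_semiaxes,gdce_semiaxes,necrosis_semiaxes mm.
#' @param vial_radius_mm,vial_length_mm Vial cylinder geometry (axis along z).
#' @param vial_centers_xy 2x2 matrix of vial axis positions (x, y) in mm.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = 64,
                         voxel_mm = 3,
                         concentrations = NULL,
                         vial_percents = c(0.3, 0.6),
                         with_gdce = TRUE,
                         with_necrosis = TRUE,
                         brain_center = c(90, 96, 96),
                         brain_semiaxes = c(60, 72, 60),
                         tumor_center = c(105, 112, 96),
                         edema_semiaxes = c(30, 27, 24),
                         gdce_semiaxes = c(18, 15, 14),
                         necrosis_semiaxes = c(9, 8, 7),
                         vial_radius_mm = 7.5,
                         vial_length_mm = 60,
                         vial_centers_xy = rbind(c(171, 60), c(171, 132))) {
  if (is.null(concentrations)) {
    ref <- sodium_reference_values()
    concentrations <- stats::setNames(ref$mean_mM, ref$region)
  }
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  stopifnot(all(grid_shape >= 8), voxel_mm > 0,
            all(concentrations > 0),
            length(vial_percents) == 2L, all(vial_percents > 0),
            vial_percents[1] != vial_percents[2])
  spec <- list(
    grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
    concentrations = concentrations, vial_percents = vial_percents,
    with_gdce = with_gdce, with_necrosis = with_necrosis,
    brain_center = brain_center, brain_semiaxes = brain_semiaxes,
    tumor_center = tumor_center, edema_semiaxes = edema_semiaxes,
    gdce_semiaxes = gdce_semiaxes, necrosis_semiaxes = necrosis_semiaxes,
    vial_radius_mm = vial_radius_mm, vial_length_mm = vial_length_mm,
    vial_centers_xy = vial_centers_xy
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

# strict nesting: inner ellipsoid (same centre) must fit inside the outer
# with at least one voxel of clearance on every axis
validate_phantom_spec <- function(spec) {
  h <- spec$voxel_mm
  if (spec$with_necrosis && !spec$with_gdce) {
    stop("necrosis requires a gdce rim around it")
  }
  nested <- function(inner, outer) all(inner + h <= outer)
  if (spec$with_gdce && !nested(spec$gdce_semiaxes, spec$edema_semiaxes)) {
    stop("gdce ellipsoid does not nest strictly inside edema")
  }
  if (spec$with_necrosis && !nested(spec$necrosis_semiaxes, spec$gdce_semiaxes)) {
    stop("necrosis ellipsoid does not nest strictly inside gdce")
  }
  # tumor inside brain: farthest point of edema ellipsoid along each axis
  d <- abs(spec$tumor_center - spec$brain_center) + spec$edema_semiaxes
  if (any(d >= spec$brain_semiaxes)) {
    stop("edema ellipsoid extends outside the brain ellipsoid")
  }
  # vials must not intersect the brain: conservative axis-aligned check
  for (k in seq_len(nrow(spec$vial_centers_xy))) {
    cxy <- spec$vial_centers_xy[k, ]
    dx <- (abs(cxy[1] - spec$brain_center[1]) - spec$vial_radius_mm) /
      spec$brain_semiaxes[1]
    dy <- (abs(cxy[2] - spec$brain_center[2]) - spec$vial_radius_mm) /
      spec$brain_semiaxes[2]
    if (max(dx, dy) < 1) stop("reference vial intersects the brain ellipsoid")
  }
  fov <- spec$grid_shape * h
  if (any(spec$vial_centers_xy[, 1] + spec$vial_radius_mm > fov[1]) ||
      any(spec$vial_centers_xy[, 2] + spec$vial_radius_mm > fov[2])) {
    stop("reference vial extends outside the field of view")
  }
  invisible(spec)
}

phantom_label_dict <- function() {
  c(air = 0L, nawm = 1L, edema = 2L, gdce = 3L, necrosis = 4L,
    cavity = 5L, vial_lo = 6L, vial_hi = 7L)
}

# voxel-centre world coordinates per axis
axis_coords <- function(n, h) (seq_len(n) - 0.5) * h

#' Generate the synthetic phantom
#'
#' Builds the piecewise-constant ground-truth concentration volume and the
#' matching label volume from a [phantom_spec()]. Every voxel of a
#' compartment carries exactly the compartment's truth concentration; vial
#' voxels carry the sodium concentration implied by their NaCl percentage
#' (see [nacl_percent_to_mM()]); background air is 0 mM.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; jitters the tumor centre by up to one voxel so
#'   replicate phantoms are not voxel-identical. `NULL` disables jitter.
#' @return A list with elements `truth` (`na_volume`, mM) and `labels`
#'   (`na_labels`).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  validate_phantom_spec(spec)
  tumor_center <- spec$tumor_center
  if (!is.null(seed)) {
    jit <- withr::with_seed(seed, stats::runif(3, -0.5, 0.5)) * spec$voxel_mm
    tumor_center <- tumor_center + jit
    spec$tumor_center <- tumor_center
    validate_phantom_spec(spec)
  }
  n <- spec$grid_shape
  h <- spec$voxel_mm
  xs <- axis_coords(n[1], h); ys <- axis_coords(n[2], h); zs <- axis_coords(n[3], h)

  inside_ellipsoid <- function(center, semi) {
    dx2 <- ((xs - center[1]) / semi[1])^2
    dy2 <- ((ys - center[2]) / semi[2])^2
    dz2 <- ((zs - center[3]) / semi[3])^2
    outer(outer(dx2, dy2, `+`), dz2, `+`) < 1
  }

  lab <- array(0L, dim = n)
  dict <- phantom_label_dict()
  lab[inside_ellipsoid(spec$brain_center, spec$brain_semiaxes)] <- dict[["nawm"]]
  lab[inside_ellipsoid(tumor_center, spec$edema_semiaxes)] <- dict[["edema"]]
  if (spec$with_gdce) {
    lab[inside_ellipsoid(tumor_center, spec$gdce_semiaxes)] <- dict[["gdce"]]
  }
  if (spec$with_necrosis) {
    lab[inside_ellipsoid(tumor_center, spec$necrosis_semiaxes)] <- dict[["necrosis"]]
  }

  zc <- mean(zs)
  in_z <- abs(zs - zc) < spec$vial_length_mm / 2
  for (k in 1:2) {
    cxy <- spec$vial_centers_xy[k, ]
    dxy2 <- outer((xs - cxy[1])^2, (ys - cxy[2])^2, `+`)
    in_xy <- dxy2 < spec$vial_radius_mm^2
    cyl <- outer(in_xy, in_z, `&`)
    lab[cyl] <- dict[[c("vial_lo", "vial_hi")[k]]]
  }

  conc <- c(air = 0,
            spec$concentrations[c("nawm", "edema", "gdce", "necrosis")],
            cavity = 0,
            vial_lo = nacl_percent_to_mM(min(spec$vial_percents)),
            vial_hi = nacl_percent_to_mM(max(spec$vial_percents)))
  truth <- array(0, dim = n)
  for (nm in names(dict)) {
    sel <- lab == dict[[nm]]
    if (any(sel)) truth[sel] <- conc[[nm]]
  }
  present <- dict[dict %in% c(0L, unique(as.vector(lab)))]
  list(
    truth = na_volume(truth, voxel_mm = h, unit = "mM"),
    labels = na_labels(lab, voxel_mm = h, dict = present)
  )
}

#' Smooth relative transmit-field specification
#'
#' The relative transmit field f(x) (dimensionless, 1 = nominal flip) is
#' modelled as a baseline plus a Gaussian bump, the typical shape of a
#' birdcage-coil B1 profile at ultra-high field: stronger at the head centre,
#' falling off towards the periphery. Receive sensitivity is assumed equal to
#' f(x) by coil reciprocity.
#'
#' @param baseline Field value far from the bump centre.
#' @param amplitude Bump height; `baseline + amplitude` is the peak.
#' @param center_mm Bump centre in world mm (default: brain centre of the
#'   default phantom).
#' @param width_mm Gaussian width (sd) in mm.
#' @param bounds Allowed range of f; values outside raise an error.
#' @return A list of class `b1_field_spec`.
#' @export
b1_field_spec <- function(baseline = 0.9, amplitude = 0.25,
                          center_mm = c(90, 96, 96), width_mm = 90,
                          bounds = c(0.7, 1.25)) {
  stopifnot(baseline > 0, width_mm > 0, bounds[1] > 0, bounds[1] < bounds[2])
  structure(list(baseline = baseline, amplitude = amplitude,
                 center_mm = center_mm, width_mm = width_mm, bounds = bounds),
            class = "b1_field_spec")
}

#' Evaluate a B1 field specification on a grid
#'
#' @param spec A [b1_field_spec()].
#' @param like A `na_volume` or `na_labels` defining the grid.
#' @return A `na_volume` (dimensionless) with the field values.
#' @export
b1_field <- function(spec, like) {
  n <- dim(like$data); h <- like$voxel_mm
  xs <- axis_coords(n[1], h[1]); ys <- axis_coords(n[2], h[2])
  zs <- axis_coords(n[3], h[3])
  d2 <- outer(outer((xs - spec$center_mm[1])^2, (ys - spec$center_mm[2])^2, `+`),
              (zs - spec$center_mm[3])^2, `+`)
  f <- spec$baseline + spec$amplitude * exp(-d2 / (2 * spec$width_mm^2))
  if (min(f) < spec$bounds[1] || max(f) > spec$bounds[2]) {
    stop(sprintf("B1 field leaves its stated bounds [%g, %g]: range [%g, %g]",
                 spec$bounds[1], spec$bounds[2], min(f), max(f)))
  }
  na_volume(f, voxel_mm = h, unit = "")
}

#' Acquisition parameters
#'
#' @param nominal_flip_deg Nominal flip angle of the base image in degrees;
#'   the double-angle companion uses twice this value.
#' @param tr_ms,te_ms Repetition and echo time in ms. The signal model
#'   assumes full longitudinal relaxation (TR much longer than sodium T1)
#'   and neglects T2* decay over TE.
#' @param gain Global scanner gain (kappa, a.u. per mM); absorbed by the
#'   vial calibration downstream.
#' @return A list of class `acq_spec`.
#' @export
acq_spec <- function(nominal_flip_deg = 60, tr_ms = 160, te_ms = 0.35,
                     gain = 1) {
  stopifnot(nominal_flip_deg > 0, nominal_flip_deg <= 90, tr_ms > 0,
            te_ms >= 0, gain > 0)
  structure(list(nominal_flip_deg = nominal_flip_deg, tr_ms = tr_ms,
                 te_ms = te_ms, gain = gain),
            class = "acq_spec")
}

#' Simulate the double-angle sodium signal pair
#'
#' Forward model for a spin-density-weighted sodium acquisition with a
#' spatially varying transmit field and reciprocal receive sensitivity:
#' \deqn{S(\alpha_{nom}) = \kappa \, C(x) \, f(x) \, \sin(f(x)\,\alpha_{nom})}
#' and the companion image at twice the nominal flip. One factor of f(x) is
#' the receive sensitivity (reciprocity), the sine carries the actual flip.
#' Rician noise is applied per voxel on both magnitude images when
#' `sigma > 0` (independent draws per image).
#'
#' @param truth `na_volume` of true concentration (mM).
#' @param b1 A [b1_field_spec()] or a precomputed dimensionless `na_volume`.
#' @param acq An [acq_spec()].
#' @param sigma Rician noise level in a.u.; 0 for noiseless.
#' @param seed Integer seed for the noise draws (required when sigma > 0).
#' @return List with `S_alpha`, `S_2alpha` (a.u.) and `f_true`
#'   (dimensionless `na_volume`).
#' @export
simulate_signal <- function(truth, b1 = b1_field_spec(), acq = acq_spec(),
                            sigma = 0, seed = NULL) {
  check_unit(truth, "mM", "truth volume")
  stopifnot(sigma >= 0)
  f <- if (inherits(b1, "b1_field_spec")) b1_field(b1, truth) else b1
  check_same_grid(truth, f)
  a <- acq$nominal_flip_deg * pi / 180
  s1 <- acq$gain * truth$data * f$data * sin(f$data * a)
  s2 <- acq$gain * truth$data * f$data * sin(f$data * 2 * a)
  if (sigma > 0) {
    if (is.null(seed)) stop("a seed is required for noisy simulation")
    nv <- length(s1)
    noise <- withr::with_seed(seed, stats::rnorm(4 * nv, sd = sigma))
    s1 <- sqrt((s1 + noise[1:nv])^2 + noise[(nv + 1):(2 * nv)]^2)
    s2 <- sqrt((s2 + noise[(2 * nv + 1):(3 * nv)])^2 +
                 noise[(3 * nv + 1):(4 * nv)]^2)
    dim(s1) <- dim(s2) <- dim(truth$data)
  }
  list(S_alpha = na_volume(s1, truth$voxel_mm, "a.u."),
       S_2alpha = na_volume(s2, truth$voxel_mm, "a.u."),
       f_true = f)
}

#' Rician noise level for a target nawm signal-to-noise ratio
#'
#' Computes sigma so that the mean noiseless base-image signal over nawm
#' divided by sigma equals `snr` (default 20, a typical sodium-MRI value).
#'
#' @param truth,labels Phantom truth and labels.
#' @param b1,acq Field and acquisition used for the simulation.
#' @param snr Target SNR in nawm.
#' @return Scalar sigma in a.u.
#' @export
sigma_for_snr <- function(truth, labels, b1 = b1_field_spec(),
                          acq = acq_spec(), snr = 20) {
  stopifnot(snr > 0)
  sim <- simulate_signal(truth, b1 = b1, acq = acq, sigma = 0)
  m <- region_mask(labels, "nawm")
  mean(sim$S_alpha$data[m]) / snr
}

#' Inject a spherical hotspot into the edema compartment
#'
#' Raises a spherical region of the truth volume by `offset_mM`. The sphere
#' must lie strictly inside the edema compartment; this constructs positive
#' cases for the hotspot detector.
#'
#' @param truth `na_volume` (mM).
#' @param labels Matching `na_labels` with an `edema` region.
#' @param offset_mM Concentration increment (mM); 0 is a no-op.
#' @param radius_vox Sphere radius in voxels.
#' @param center_vox Sphere centre as a voxel index triple; must be an edema
#'   voxel and the whole sphere must fit inside edema.
#' @return Modified truth `na_volume`.
#' @export
inject_hotspot <- function(truth, labels, offset_mM, radius_vox, center_vox) {
  check_unit(truth, "mM", "truth volume")
  check_same_grid(truth, labels)
  edema <- region_mask(labels, "edema")
  n <- dim(truth$data)
  stopifnot(length(center_vox) == 3L, all(center_vox >= 1),
            all(center_vox <= n))
  if (!edema[center_vox[1], center_vox[2], center_vox[3]]) {
    stop("hotspot centre is not inside the edema compartment")
  }
  d2 <- outer(outer((seq_len(n[1]) - center_vox[1])^2,
                    (seq_len(n[2]) - center_vox[2])^2, `+`),
              (seq_len(n[3]) - center_vox[3])^2, `+`)
  sphere <- d2 <= radius_vox^2
  if (any(sphere & !edema)) {
    stop("hotspot sphere of radius ", radius_vox,
         " voxels does not fit inside the edema compartment")
  }
  out <- truth
  out$data[sphere] <- out$data[sphere] + offset_mM
  out
}
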