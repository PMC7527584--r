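# Small 32^3 phantom (half-scale geometry) for fast tests.
small_spec <- function(...) {
  args <- list(
    grid_shape = 32, voxel_mm = 3,
    brain_center = c(45, 48, 48), brain_semiaxes = c(30, 36, 30),
    tumor_center = c(52, 56, 48),
    edema_semiaxes = c(15, 13.5, 12),
    gdce_semiaxes = c(9, 7.5, 7),
    necrosis_semiaxes = c(4.5, 4, 3.5),
    vial_radius_mm = 6, vial_length_mm = 30,
    vial_centers_xy = rbind(c(85, 30), c(85, 66))
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

# 64^3 phantom with a thick edema shell so injected spheres fit.
thick_edema_spec <- function(...) {
  phantom_spec(edema_semiaxes = c(39, 36, 33), ...)
}

# Exact search for an edema voxel where a sphere of `radius` voxels fits
# strictly inside edema; prefer = "far"/"near" relative to gdce.
find_sphere_center <- function(labels, radius, prefer = "far") {
  edema <- region_mask(labels, "edema")
  # distance to the non-edema boundary shell suffices for fit checking
  outside <- which(sodiumap:::dilate_26(edema) & !edema, arr.ind = TRUE)
  cand <- which(edema, arr.ind = TRUE)
  d_out <- apply(cand, 1, function(v) {
    sqrt(min(colSums((t(outside) - v)^2)))
  })
  ok <- d_out > radius
  if (!any(ok)) stop("no sphere of that radius fits inside edema")
  cand <- cand[ok, , drop = FALSE]
  gd <- which(region_mask(labels, "gdce"), arr.ind = TRUE)
  d_g <- apply(cand, 1, function(v) sqrt(min(colSums((t(gd) - v)^2))))
  i <- if (prefer == "far") which.max(d_g) else which.min(d_g)
  cand[i, ]
}

# Box-world labels for controlled hotspot tests: an edema slab with an
# optional gdce slab glued to its x-max face.
box_labels <- function(n = c(24, 16, 8), edema_x = 1:16, gdce_x = NULL,
                       voxel_mm = 3) {
  lab <- array(0L, n)
  lab[edema_x, , ] <- 2L
  dict <- c(air = 0L, edema = 2L)
  if (!is.null(gdce_x)) {
    lab[gdce_x, , ] <- 3L
    dict <- c(dict, gdce = 3L)
  }
  na_labels(lab, voxel_mm = voxel_mm, dict = dict)
}

constant_volume <- function(labels, value = 50, unit = "mM") {
  na_volume(array(value, dim(labels$data)), labels$voxel_mm, unit)
}
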