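#' Estimate the relative transmit field with the double-angle method
#'
#' With full longitudinal relaxation (long TR), the signal ratio of two
#' acquisitions at nominal flips alpha and 2*alpha satisfies
#' S(2a)/(2 S(a)) = cos(f a), so the actual flip per voxel is
#' \deqn{\hat\alpha = \arccos\!\big(S_{2\alpha} / (2 S_\alpha)\big)}
#' and the relative transmit field is f = actual / nominal flip.
#'
#' Voxels whose base signal falls below `snr_floor`, or whose ratio leaves
#' the arccos domain (clamped to `[eps, 1 - eps]`), are marked invalid;
#' downstream correction treats them as f = 1 (pass-through) so ROI
#' statistics never silently lose voxels.
#'
#' @param S_alpha,S_2alpha `na_volume`s (a.u.) at nominal flip and twice it.
#' @param acq [acq_spec()]; `nominal_flip_deg` is the flip of `S_alpha`.
#' @param snr_floor Signal floor in a.u. below which estimation is skipped.
#' @param eps Clamp margin for the arccos argument.
#' @param smooth_mm Gaussian smoothing width (sd, mm) applied to the
#'   estimated field over valid voxels; 0 (default) disables smoothing.
#'   The transmit field varies on the scale of the coil, so smoothing
#'   suppresses voxelwise noise without biasing the field estimate.
#' @return A list of class `b1_map`: `f` (dimensionless `na_volume`) and
#'   `valid` (logical array).
#' @export
fit_double_angle <- function(S_alpha, S_2alpha, acq = acq_spec(),
                             snr_floor = 0, eps = 1e-6, smooth_mm = 0) {
  check_unit(S_alpha, "a.u.", "S_alpha")
  check_unit(S_2alpha, "a.u.", "S_2alpha")
  check_same_grid(S_alpha, S_2alpha)
  a_nom <- acq$nominal_flip_deg * pi / 180
  r <- S_2alpha$data / (2 * S_alpha$data)
  valid <- S_alpha$data >= snr_floor & is.finite(r) &
    r >= eps & r <= 1 - eps
  r <- pmin(pmax(r, eps), 1 - eps)
  f <- acos(r) / a_nom
  f[!valid] <- 1
  dim(f) <- dim(S_alpha$data)
  dim(valid) <- dim(S_alpha$data)
  if (!any(valid)) {
    warning("double-angle estimation failed at every voxel; returning f = 1")
  }
  if (smooth_mm > 0 && any(valid)) {
    # validity-weighted smoothing so invalid (f = 1) voxels do not bleed in
    w <- gauss_smooth_3d(array(as.numeric(valid), dim(valid)),
                         smooth_mm / S_alpha$voxel_mm)
    fs <- gauss_smooth_3d(f * valid, smooth_mm / S_alpha$voxel_mm)
    ok <- valid & w > 1e-8
    f[ok] <- fs[ok] / w[ok]
  }
  structure(
    list(f = na_volume(f, S_alpha$voxel_mm, ""), valid = valid,
         nominal_flip_deg = acq$nominal_flip_deg),
    class = "b1_map"
  )
}

# separable 3D Gaussian filter; sigma_vox per axis (recycled), truncated
# at 3 sigma, zero-padded boundaries (callers renormalize by a smoothed
# weight volume)
gauss_smooth_3d <- function(a, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    a <- convolve_axis(a, k, ax)
  }
  a
}

convolve_axis <- function(a, k, ax) {
  n <- dim(a)
  half <- (length(k) - 1L) / 2L
  out <- array(0, n)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- seq_len(n[ax]) + off
    keep <- src >= 1 & src <= n[ax]
    if (!any(keep)) next
    dst_idx <- lapply(n, seq_len); src_idx <- dst_idx
    dst_idx[[ax]] <- which(keep); src_idx[[ax]] <- src[keep]
    out[dst_idx[[1]], dst_idx[[2]], dst_idx[[3]]] <-
      out[dst_idx[[1]], dst_idx[[2]], dst_idx[[3]]] +
      k[j] * a[src_idx[[1]], src_idx[[2]], src_idx[[3]]]
  }
  out
}

#' @export
print.b1_map <- function(x, ...) {
  cat(sprintf("<b1_map> %s voxels, %.1f%% valid, f range [%.3f, %.3f]\n",
              paste(dim(x$f$data), collapse = " x "),
              100 * mean(x$valid),
              min(x$f$data[x$valid]), max(x$f$data[x$valid])))
  invisible(x)
}

#' Correct signal for transmit and receive inhomogeneity
#'
#' Applies the reciprocity-based correction
#' \deqn{S_{corr} = S \cdot \frac{\sin\alpha_{nom}}{f \, \sin(f\,\alpha_{nom})}}
#' where one factor of f removes the receive sensitivity (receive field
#' equals transmit field for a birdcage coil) and the sine ratio removes the
#' actual-flip weighting. Invalid voxels pass through unchanged. Voxels
#' where the actual flip reaches 180 degrees are additionally invalidated
#' (the sine changes sign there and the correction is ambiguous).
#'
#' @param S_alpha `na_volume` (a.u.) at the nominal flip.
#' @param b1 A `b1_map` from [fit_double_angle()] (or any object with an
#'   `f` volume and a `valid` array).
#' @param acq [acq_spec()] matching the acquisition of `S_alpha`.
#' @return Corrected `na_volume` (a.u.) with attribute `n_invalid`, the
#'   number of pass-through voxels.
#' @export
correct_signal <- function(S_alpha, b1, acq = acq_spec()) {
  check_unit(S_alpha, "a.u.", "signal volume")
  check_same_grid(S_alpha, b1$f)
  a_nom <- acq$nominal_flip_deg * pi / 180
  f <- b1$f$data
  valid <- b1$valid & (f * a_nom < pi)
  out <- S_alpha$data
  out[valid] <- S_alpha$data[valid] * sin(a_nom) /
    (f[valid] * sin(f[valid] * a_nom))
  res <- na_volume(out, S_alpha$voxel_mm, "a.u.")
  attr(res, "n_invalid") <- sum(!valid)
  res
}
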