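#' Sodium concentration of a NaCl solution
#'
#' Converts NaCl content in % w/v (grams per 100 mL) to sodium
#' concentration in mM, assuming complete dissociation so that the sodium
#' concentration equals the NaCl concentration. Molar mass of NaCl:
#' 58.44 g/mol.
#'
#' @param percent NaCl content, % w/v (non-negative).
#' @return Concentration in mM; 0.3% -> 51.33 mM, 0.6% -> 102.67 mM.
#' @export
nacl_percent_to_mM <- function(percent) {
  if (any(percent < 0)) stop("NaCl percentage must be non-negative")
  percent * 10 / 58.44 * 1000
}

#' Fit the two-point vial calibration line
#'
#' The affine map from B1-corrected signal (a.u.) to absolute sodium
#' concentration (mM) is the line through the two reference-vial points
#' (mean vial signal, known vial concentration). With exactly two
#' references this interpolating line is the unique fit; the intercept is
#' retained to absorb offset-like bias. Vial masks are eroded by one voxel
#' (6-neighbourhood) before averaging to avoid edge partial-volume voxels.
#'
#' @param S_corr Corrected signal `na_volume` (a.u.).
#' @param labels `na_labels` containing `vial_lo` and `vial_hi` regions.
#' @param vial_percents NaCl % w/v of the low and high vial.
#' @param erode Erode vial masks by one voxel before averaging (default
#'   TRUE).
#' @param min_voxels Minimum usable voxels per vial after erosion.
#' @return A list of class `na_calibration`: `slope` (mM per a.u.),
#'   `intercept` (mM), and per-vial QC (`vial_mean`, `vial_sd`, `vial_n`,
#'   `vial_mM`).
#' @export
fit_calibration <- function(S_corr, labels, vial_percents = c(0.3, 0.6),
                            erode = TRUE, min_voxels = 10) {
  check_unit(S_corr, "a.u.", "corrected signal")
  check_same_grid(S_corr, labels)
  conc <- nacl_percent_to_mM(sort(vial_percents))
  stats_for <- function(region) {
    if (!region %in% names(labels$dict)) {
      stop("calibration requires a '", region, "' region in the label volume")
    }
    m <- region_mask(labels, region)
    if (erode) {
      me <- erode_mask(m)
      if (sum(me) >= min_voxels) m <- me
    }
    n <- sum(m)
    if (n < min_voxels) {
      stop("vial '", region, "' has ", n, " voxels; need at least ", min_voxels)
    }
    v <- S_corr$data[m]
    c(mean = mean(v), sd = stats::sd(v), n = n)
  }
  lo <- stats_for("vial_lo")
  hi <- stats_for("vial_hi")
  if (abs(hi[["mean"]] - lo[["mean"]]) < 1e-9 * max(1, abs(hi[["mean"]]))) {
    stop("degenerate calibration: vial mean signals are equal")
  }
  slope <- (conc[2] - conc[1]) / (hi[["mean"]] - lo[["mean"]])
  if (slope <= 0) stop("calibration slope is non-positive; check vial labels")
  structure(
    list(slope = slope,
         intercept = conc[1] - slope * lo[["mean"]],
         vial_mean = c(lo = lo[["mean"]], hi = hi[["mean"]]),
         vial_sd = c(lo = lo[["sd"]], hi = hi[["sd"]]),
         vial_n = c(lo = lo[["n"]], hi = hi[["n"]]),
         vial_mM = c(lo = conc[1], hi = conc[2])),
    class = "na_calibration"
  )
}

# binary erosion by one voxel, 6-neighbourhood
erode_mask <- function(m) {
  n <- dim(m)
  out <- m
  shift_and <- function(axis, by) {
    s <- array(FALSE, n)
    idx_src <- lapply(n, seq_len)
    idx_dst <- idx_src
    rng <- seq_len(n[axis] - abs(by))
    if (by > 0) { idx_dst[[axis]] <- rng + by; idx_src[[axis]] <- rng }
    else { idx_dst[[axis]] <- rng; idx_src[[axis]] <- rng + abs(by) }
    s[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    s
  }
  for (axis in 1:3) {
    out <- out & shift_and(axis, 1) & shift_and(axis, -1)
  }
  out
}

#' @export
print.na_calibration <- function(x, ...) {
  cat(sprintf("<na_calibration> mM = %.4g * S + %.4g\n", x$slope, x$intercept))
  cat(sprintf("  vials: %.4g a.u. -> %.4g mM (n=%d), %.4g a.u. -> %.4g mM (n=%d)\n",
              x$vial_mean[["lo"]], x$vial_mM[["lo"]], x$vial_n[["lo"]],
              x$vial_mean[["hi"]], x$vial_mM[["hi"]], x$vial_n[["hi"]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_calibration
#' @param x A `na_calibration`.
#' @param ... Unused.
#' @export
tidy.na_calibration <- function(x, ...) {
  tibble::tibble(
    vial = c("lo", "hi"),
    signal_mean = unname(x$vial_mean),
    signal_sd = unname(x$vial_sd),
    n_voxels = unname(x$vial_n),
    concentration_mM = unname(x$vial_mM)
  )
}

#' @rdname fit_calibration
#' @export
glance.na_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept)
}

#' Apply a calibration line to a corrected-signal volume
#'
#' Voxelwise affine map to mM. Negative outputs (possible under noise) are
#' floored at zero by default; the count of floored voxels is reported in
#' the `n_floored` attribute.
#'
#' @param S_corr Corrected signal `na_volume` (a.u.).
#' @param line A `na_calibration` from [fit_calibration()].
#' @param floor_negative Floor negative concentrations at 0 (default TRUE).
#' @return Concentration `na_volume` (mM).
#' @export
apply_calibration <- function(S_corr, line, floor_negative = TRUE) {
  check_unit(S_corr, "a.u.", "corrected signal")
  stopifnot(inherits(line, "na_calibration"))
  out <- line$slope * S_corr$data + line$intercept
  n_floored <- 0L
  if (floor_negative) {
    neg <- out < 0
    n_floored <- sum(neg)
    out[neg] <- 0
  }
  res <- na_volume(out, S_corr$voxel_mm, "mM")
  attr(res, "n_floored") <- n_floored
  res
}

#' Full quantification chain on a double-angle pair
#'
#' Convenience wrapper: double-angle B1 estimation, reciprocity-based
#' signal correction, two-point vial calibration, calibration application.
#'
#' @param S_alpha,S_2alpha Signal pair (a.u.).
#' @param labels `na_labels` with vial regions.
#' @param acq [acq_spec()].
#' @param vial_percents NaCl % w/v of the vials.
#' @param snr_floor Passed to [fit_double_angle()].
#' @return List: `concentration` (`na_volume`, mM), `b1` (`b1_map`),
#'   `calibration` (`na_calibration`).
#' @export
quantify_sodium <- function(S_alpha, S_2alpha, labels, acq = acq_spec(),
                            vial_percents = c(0.3, 0.6), snr_floor = 0) {
  b1 <- fit_double_angle(S_alpha, S_2alpha, acq = acq, snr_floor = snr_floor)
  S_corr <- correct_signal(S_alpha, b1, acq = acq)
  line <- fit_calibration(S_corr, labels, vial_percents = vial_percents)
  conc <- apply_calibration(S_corr, line)
  list(concentration = conc, b1 = b1, calibration = line)
}
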