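#' Create a scalar image volume
#'
#' A `na_volume` is a 3D scalar grid with an isotropic-or-not voxel size in
#' millimetres and a unit tag. Units are tracked explicitly ("a.u." for raw
#' scanner signal, "mM" for calibrated sodium concentration, "" for
#' dimensionless fields) and enforced at pipeline stage boundaries, because
#' the quantification chain silently changes units at calibration.
#'
#' @param data Numeric 3D array of voxel values.
#' @param voxel_mm Voxel edge lengths in mm; length 1 (isotropic) or 3.
#' @param unit Unit tag, one of `"a.u."`, `"mM"`, `""`.
#' @return An object of class `na_volume`.
#' @export
na_volume <- function(data, voxel_mm = 3, unit = "a.u.") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0))
  if (!unit %in% c("a.u.", "mM", "")) {
    stop("unit must be one of 'a.u.', 'mM', ''")
  }
  structure(
    list(data = data, voxel_mm = as.numeric(voxel_mm), unit = unit),
    class = "na_volume"
  )
}

#' Create a label volume
#'
#' Integer compartment/vial masks sharing a voxel grid with an image. The
#' label dictionary maps region names to the integer codes stored in the
#' array; code 0 is always background (air).
#'
#' @param data Integer 3D array of label codes.
#' @param voxel_mm Voxel edge lengths in mm; length 1 or 3.
#' @param dict Named integer vector mapping region names to codes.
#' @return An object of class `na_labels`.
#' @export
na_labels <- function(data, voxel_mm = 3, dict) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  storage.mode(data) <- "integer"
  stopifnot(!is.null(names(dict)), !anyDuplicated(dict), !anyDuplicated(names(dict)))
  present <- setdiff(unique(as.vector(data)), 0L)
  if (!all(present %in% dict)) {
    stop("label volume contains codes absent from the dictionary: ",
         paste(setdiff(present, dict), collapse = ", "))
  }
  structure(
    list(data = data, voxel_mm = as.numeric(voxel_mm),
         dict = vapply(dict, as.integer, integer(1))),
    class = "na_labels"
  )
}

#' @export
print.na_volume <- function(x, ...) {
  cat(sprintf("<na_volume> %s voxels, %.3g x %.3g x %.3g mm, unit '%s'\n",
              paste(dim(x$data), collapse = " x "),
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3], x$unit))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.na_labels <- function(x, ...) {
  cat(sprintf("<na_labels> %s voxels, %.3g mm\n",
              paste(dim(x$data), collapse = " x "), x$voxel_mm[1]))
  counts <- table(factor(x$data, levels = x$dict,
                         labels = names(x$dict)))
  print(counts)
  invisible(x)
}

#' @export
dim.na_volume <- function(x) dim(x$data)

#' @export
dim.na_labels <- function(x) dim(x$data)

#' Voxel volume in millilitres
#' @param x A `na_volume` or `na_labels`.
#' @return Scalar, mL per voxel.
#' @export
voxel_ml <- function(x) prod(x$voxel_mm) / 1000

#' Extract the binary mask for a named region
#' @param labels A `na_labels` object.
#' @param region Region name present in the label dictionary.
#' @return Logical 3D array.
#' @export
region_mask <- function(labels, region) {
  stopifnot(inherits(labels, "na_labels"))
  if (!region %in% names(labels$dict)) {
    stop("region '", region, "' not in label dictionary")
  }
  labels$data == labels$dict[[region]]
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$voxel_mm - b$voxel_mm)) > 1e-9) {
    stop("volumes are not on the same grid")
  }
  invisible(TRUE)
}

check_unit <- function(vol, unit, what = "input") {
  if (!identical(vol$unit, unit)) {
    stop(sprintf("%s must be in '%s' but has unit '%s'", what, unit, vol$unit),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a volume to a NIfTI-1 file
#'
#' The unit tag and (for label volumes) the label dictionary are written to a
#' JSON sidecar next to the image so round trips preserve semantics.
#'
#' @param vol A `na_volume` or `na_labels`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, pixdim = vol$voxel_mm)
  RNifti::writeNifti(img, path)
  side <- if (inherits(vol, "na_labels")) {
    list(kind = "labels", voxel_mm = vol$voxel_mm, dict = as.list(vol$dict))
  } else {
    list(kind = "volume", voxel_mm = vol$voxel_mm, unit = vol$unit)
  }
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#' @param path Path to the NIfTI file.
#' @return A `na_volume` or `na_labels`, depending on the sidecar.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (identical(side$kind, "labels")) {
    na_labels(arr, voxel_mm = side$voxel_mm, dict = unlist(side$dict))
  } else {
    na_volume(arr, voxel_mm = side$voxel_mm, unit = side$unit)
  }
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Plot an axial slice of a volume
#'
#' @param vol A `na_volume`.
#' @param z Slice index along the third axis (default: middle slice).
#' @param labels Optional `na_labels` whose non-zero outline is overdrawn.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, z = NULL, labels = NULL) {
  stopifnot(inherits(vol, "na_volume"))
  if (is.null(z)) z <- ceiling(dim(vol$data)[3] / 2)
  sl <- vol$data[, , z]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- sl[cbind(df$x, df$y)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = vol$unit) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("axial slice z = %d", z)) +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    lab <- labels$data[, , z]
    df$region <- factor(lab[cbind(df$x, df$y)], levels = labels$dict,
                        labels = names(labels$dict))
    outline <- df[!is.na(df$region) & df$region != "air", , drop = FALSE]
    if (nrow(outline)) {
      p <- p + ggplot2::geom_point(
        data = outline,
        mapping = ggplot2::aes(x = .data$x, y = .data$y, colour = .data$region),
        size = 0.1, inherit.aes = FALSE
      )
    }
  }
  p
}
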