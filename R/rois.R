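#' Resample a label volume onto a target grid
#'
#' Nearest-neighbour resampling of a categorical mask onto the grid of a
#' (typically coarser) sodium image. Both grids are assumed co-registered
#' and to share the world origin at the corner of voxel (1,1,1); each
#' target voxel takes the label of the source voxel containing its centre.
#' Labels can disappear (a region smaller than a target voxel) but no new
#' labels appear; a region that vanishes entirely triggers a warning.
#'
#' @param mask `na_labels` on the source grid.
#' @param target A `na_volume` or `na_labels` defining the target grid.
#' @return `na_labels` on the target grid.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "na_labels"))
  if (identical(dim(mask$data), dim(target$data)) &&
      max(abs(mask$voxel_mm - target$voxel_mm)) < 1e-9) {
    return(mask)
  }
  nt <- dim(target$data); ns <- dim(mask$data)
  idx <- lapply(1:3, function(ax) {
    centers <- axis_coords(nt[ax], target$voxel_mm[ax])
    i <- ceiling(centers / mask$voxel_mm[ax])
    pmin(pmax(i, 1L), ns[ax])
  })
  out <- mask$data[idx[[1]], idx[[2]], idx[[3]]]
  dim(out) <- nt
  before <- setdiff(unique(as.vector(mask$data)), 0L)
  after <- setdiff(unique(as.vector(out)), 0L)
  lost <- setdiff(before, after)
  if (length(lost)) {
    warning("resampling lost label(s): ",
            paste(names(mask$dict)[match(lost, mask$dict)], collapse = ", "))
  }
  na_labels(out, voxel_mm = target$voxel_mm, dict = mask$dict)
}

#' Compose separate compartment masks into one label volume
#'
#' Radiologist masks are drawn per compartment and may overlap at
#' boundaries. Composition applies center-out precedence — necrosis over
#' gdce over edema (the innermost compartment wins) — and reports how many
#' voxels were reassigned. A nawm reference ROI overlapping any tumor
#' compartment is rejected: the reference must be normal-appearing tissue.
#'
#' @param edema Logical 3D array (required).
#' @param gdce,necrosis,cavity,nawm Optional logical arrays on the same
#'   grid.
#' @param voxel_mm Voxel size in mm.
#' @return `na_labels` with the composed, disjoint label volume.
#' @export
build_segmentation <- function(edema, gdce = NULL, necrosis = NULL,
                               cavity = NULL, nawm = NULL, voxel_mm = 3) {
  stopifnot(is.array(edema))
  empty <- array(FALSE, dim(edema))
  gdce <- gdce %||% empty; necrosis <- necrosis %||% empty
  cavity <- cavity %||% empty; nawm <- nawm %||% empty
  tumor <- edema | gdce | necrosis
  if (any(nawm & (tumor | cavity))) {
    stop("nawm reference ROI overlaps a tumor compartment or cavity")
  }
  overlap <- sum(edema & gdce) + sum(gdce & necrosis) + sum(edema & necrosis)
  if (overlap > 0) {
    message(overlap, " overlapping voxel(s) reassigned by precedence ",
            "necrosis > gdce > edema")
  }
  dict <- phantom_label_dict()
  lab <- array(0L, dim(edema))
  lab[nawm] <- dict[["nawm"]]
  lab[edema] <- dict[["edema"]]
  lab[gdce] <- dict[["gdce"]]
  lab[necrosis] <- dict[["necrosis"]]
  lab[cavity] <- dict[["cavity"]]
  keep <- dict[dict %in% c(0L, unique(as.vector(lab)))]
  na_labels(lab, voxel_mm = voxel_mm, dict = keep)
}

#' Merge single-slice nawm ROIs
#'
#' The contralateral normal-appearing white matter reference is drawn as
#' one ROI on each of up to three slices; their voxel union forms the nawm
#' region used for statistics. Duplicated voxels count once.
#'
#' @param rois List of logical 3D arrays (or a single array) on one grid.
#' @param voxel_mm Voxel size of the grid.
#' @return `na_labels` with a single `nawm` region.
#' @export
merge_nawm <- function(rois, voxel_mm = 3) {
  if (is.array(rois)) rois <- list(rois)
  if (length(rois) == 0L) stop("at least one nawm ROI is required")
  acc <- Reduce(`|`, rois)
  na_labels(array(as.integer(acc), dim(acc)), voxel_mm = voxel_mm,
            dict = c(air = 0L, nawm = 1L))
}

#' Build the whole-tumor mask
#'
#' The whole tumor volume is the union of the contrast-enhancing region and
#' the peritumoral edema, minus necrosis and any resection cavity. Necrosis
#' is excluded to avoid the confounding cerebrospinal-fluid signal; the
#' cavity is post-surgical and never analysed.
#'
#' @param labels `na_labels` whose dictionary may contain `gdce`, `edema`,
#'   `necrosis`, `cavity`.
#' @return `na_labels` with a single `whole_tumor` region.
#' @export
whole_tumor <- function(labels) {
  stopifnot(inherits(labels, "na_labels"))
  get <- function(r) {
    if (r %in% names(labels$dict)) region_mask(labels, r)
    else array(FALSE, dim(labels$data))
  }
  m <- (get("gdce") | get("edema")) & !get("necrosis") & !get("cavity")
  if (!any(m)) stop("whole-tumor mask is empty")
  na_labels(array(as.integer(m), dim(m)), voxel_mm = labels$voxel_mm,
            dict = c(air = 0L, whole_tumor = 1L))
}

#' Per-region summary statistics of a concentration map
#'
#' Mean, SD, median and volume of the concentration over each requested
#' region. Regions absent from the label dictionary, or present but empty,
#' are omitted from the output (absent, not zero), so per-comparison Ns in
#' downstream group statistics reflect true compartment presence.
#'
#' @param conc Concentration `na_volume` (mM).
#' @param labels `na_labels` on the same grid.
#' @param regions Region names to summarise; default: all non-air regions
#'   in the dictionary.
#' @return Tibble: `region`, `n_voxels`, `volume_ml`, `mean`, `sd`,
#'   `median` (mM).
#' @export
region_stats <- function(conc, labels, regions = NULL) {
  check_unit(conc, "mM", "concentration map")
  check_same_grid(conc, labels)
  if (is.null(regions)) regions <- setdiff(names(labels$dict), "air")
  vml <- voxel_ml(labels)
  rows <- purrr::map(regions, function(r) {
    if (!r %in% names(labels$dict)) return(NULL)
    m <- region_mask(labels, r)
    n <- sum(m)
    if (n == 0L) return(NULL)
    v <- conc$data[m]
    tibble::tibble(region = r, n_voxels = n, volume_ml = n * vml,
                   mean = mean(v), sd = stats::sd(v), median = stats::median(v))
  })
  dplyr::bind_rows(rows)
}

#' Normalize region means to the nawm mean
#'
#' @param stats Tibble from [region_stats()] including a `nawm` row.
#' @return The input with an added `mean_norm` column (region mean divided
#'   by the nawm mean, dimensionless).
#' @export
normalize_to_nawm <- function(stats) {
  stopifnot(is.data.frame(stats), "nawm" %in% stats$region)
  nawm_mean <- stats$mean[stats$region == "nawm"][1]
  if (!is.finite(nawm_mean) || nawm_mean <= 0) {
    stop("nawm mean must be positive for normalization")
  }
  dplyr::mutate(stats, mean_norm = .data$mean / nawm_mean)
}
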