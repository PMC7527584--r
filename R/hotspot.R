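#' Detect sodium hotspots inside the peritumoral edema
#'
#' Semiquantitative hotspot criterion: an intensity window is set two
#' standard deviations around the per-patient mean edema concentration.
#' Edema voxels whose concentration lies strictly above the upper frame
#' (mean + 2 SD) are grouped into 26-connected components. Components
#' smaller than `min_size` voxels are discarded as noise; a component is
#' also excluded when it abuts the contrast-enhancing region — specifically
#' when the fraction of its voxels lying within one voxel
#' (26-neighbourhood) of gdce exceeds `adjacency_threshold`. The patient is
#' hotspot-positive when at least one component is retained.
#'
#' @param conc Concentration `na_volume` (mM).
#' @param labels `na_labels` with an `edema` region; a `gdce` region is
#'   optional (absent gdce makes the adjacency rule vacuous).
#' @param min_size Minimum component size in voxels (default 5).
#' @param adjacency_threshold Maximum tolerated gdce-adjacent voxel
#'   fraction (default 0.25).
#' @return A list of class `na_hotspots`: `window_low`/`window_high` (mM),
#'   `components` (tibble: size, centroid, mean mM, adjacency fraction,
#'   retained flag), `patient_positive`, and `component_labels`
#'   (`na_labels` of retained components).
#' @export
detect_hotspots <- function(conc, labels, min_size = 5,
                            adjacency_threshold = 0.25) {
  check_unit(conc, "mM", "concentration map")
  check_same_grid(conc, labels)
  edema <- region_mask(labels, "edema")
  if (!any(edema)) stop("edema region is empty")
  v <- conc$data[edema]
  mu <- mean(v); sdv <- stats::sd(v)
  if (!is.finite(sdv)) sdv <- 0
  hi <- mu + 2 * sdv; lo <- mu - 2 * sdv

  supra <- edema & conc$data > hi
  # a numerically constant edema (sd at rounding level) has no hotspots:
  # nothing exceeds a collapsed window beyond measurement precision
  if (sdv <= 1e-9 * max(abs(mu), 1)) supra[] <- FALSE
  comp_lab <- label_components_26(supra)
  gdce <- if ("gdce" %in% names(labels$dict)) region_mask(labels, "gdce")
          else array(FALSE, dim(labels$data))
  near_gdce <- if (any(gdce)) dilate_26(gdce) else gdce

  ids <- setdiff(unique(as.vector(comp_lab)), 0L)
  comp <- purrr::map(ids, function(id) {
    sel <- comp_lab == id
    idx <- which(sel, arr.ind = TRUE)
    size <- nrow(idx)
    adj <- mean(near_gdce[sel])
    tibble::tibble(
      component = id, size = size,
      centroid_x = mean(idx[, 1]), centroid_y = mean(idx[, 2]),
      centroid_z = mean(idx[, 3]),
      mean_mM = mean(conc$data[sel]),
      adjacency_fraction = adj,
      retained = size >= min_size & adj <= adjacency_threshold
    )
  })
  comp <- dplyr::bind_rows(comp)
  if (nrow(comp) == 0L) {
    comp <- tibble::tibble(component = integer(), size = integer(),
                           centroid_x = numeric(), centroid_y = numeric(),
                           centroid_z = numeric(), mean_mM = numeric(),
                           adjacency_fraction = numeric(), retained = logical())
  }
  keep <- comp$component[comp$retained]
  out_lab <- array(0L, dim(comp_lab))
  for (i in seq_along(keep)) out_lab[comp_lab == keep[i]] <- i
  dict <- c(air = 0L)
  if (length(keep)) {
    dict <- c(dict, stats::setNames(seq_along(keep),
                                    paste0("hotspot_", seq_along(keep))))
  }
  structure(
    list(window_low = lo, window_high = hi, components = comp,
         patient_positive = any(comp$retained),
         component_labels = na_labels(out_lab, labels$voxel_mm, dict)),
    class = "na_hotspots"
  )
}

#' @export
print.na_hotspots <- function(x, ...) {
  cat(sprintf("<na_hotspots> window [%.2f, %.2f] mM; %d component(s), %d retained; patient %s\n",
              x$window_low, x$window_high, nrow(x$components),
              sum(x$components$retained),
              if (x$patient_positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' @rdname detect_hotspots
#' @param x A `na_hotspots` object.
#' @param ... Unused.
#' @export
tidy.na_hotspots <- function(x, ...) x$components

#' @rdname detect_hotspots
#' @export
glance.na_hotspots <- function(x, ...) {
  tibble::tibble(window_low = x$window_low, window_high = x$window_high,
                 n_components = nrow(x$components),
                 n_retained = sum(x$components$retained),
                 patient_positive = x$patient_positive)
}

# 26-neighbourhood offsets (3^3 - 1)
offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# label 26-connected components of a logical 3D array by union-find over
# the sparse foreground voxel set
label_components_26 <- function(mask) {
  n <- dim(mask)
  lin <- which(mask)
  out <- array(0L, n)
  m <- length(lin)
  if (m == 0L) return(out)
  pos <- match(seq_len(prod(n)), lin)  # linear index -> foreground rank
  idx <- arrayInd(lin, n)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- offsets_26()
  # only forward offsets to visit each pair once
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
           (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    nb <- idx + matrix(offs[k, ], nrow = m, ncol = 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= n[1] & nb[, 2] >= 1 & nb[, 2] <= n[2] &
      nb[, 3] >= 1 & nb[, 3] <= n[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1) * n[1] + (nb[ok, 3] - 1) * n[1] * n[2]
    j <- pos[nb_lin]
    src <- which(ok)[!is.na(j)]
    dst <- j[!is.na(j)]
    for (t in seq_along(src)) {
      a <- find(src[t]); b <- find(dst[t])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  out[lin] <- match(roots, unique(roots))
  out
}

# binary dilation by one voxel, 26-neighbourhood
dilate_26 <- function(mask) {
  n <- dim(mask)
  out <- mask
  offs <- offsets_26()
  lin <- which(mask)
  if (!length(lin)) return(out)
  idx <- arrayInd(lin, n)
  for (k in seq_len(nrow(offs))) {
    nb <- idx + matrix(offs[k, ], nrow = nrow(idx), ncol = 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= n[1] & nb[, 2] >= 1 & nb[, 2] <= n[2] &
      nb[, 3] >= 1 & nb[, 3] <= n[3]
    out[nb[ok, , drop = FALSE]] <- TRUE
  }
  out
}
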