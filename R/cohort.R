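#' Published biomarker group summaries
#'
#' Whole-tumor median sodium concentration summaries (median and
#' interquartile range, mM) per histopathological group in a 28-patient
#' glioma cohort: tumor grade (glioblastoma vs lower grades), IDH mutation
#' status, and MGMT promoter methylation status within the glioblastoma
#' subgroup. These are the default targets of the synthetic cohort
#' generator.
#'
#' @return A tibble with columns `comparison`, `group`, `n`, `median_mM`,
#'   `iqr_lo`, `iqr_hi`.
#' @export
glioma_group_specs <- function() {
  tibble::tribble(
    ~comparison, ~group,      ~n,  ~median_mM, ~iqr_lo, ~iqr_hi,
    "grade",     "gbm",       21L, 54.18,      46.86,   58.77,
    "grade",     "non_gbm",   7L,  66.73,      62.39,   67.66,
    "idh",       "idh_wt",    18L, 52.37,      45.98,   58.56,
    "idh",       "idh_mut",   6L,  65.02,      58.87,   67.05,
    "mgmt",      "mgmt_met",  10L, 57.59,      50.70,   59.17,
    "mgmt",      "mgmt_not",  4L,  48.78,      45.88,   53.91
  )
}

# IQR width of a normal is 1.349 sd, so sd = IQR width / 1.349
iqr_to_sd <- function(lo, hi) (hi - lo) / 1.349

rtruncnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Simulate a patient cohort
#'
#' Draws per-patient whole-tumor median sodium concentrations from
#' group-matched distributions and synthesises per-region statistics with
#' realistic missingness (not every patient has a contrast-enhancing or
#' necrotic compartment).
#'
#' Whole-tumor medians are drawn from a normal distribution with mean equal
#' to the group's target median and sd = IQR width / 1.349, truncated at
#' zero (a log-normal alternative matched by median and IQR is available via
#' `dist`). Region medians are generated from the reference compartment
#' means and SDs with a shared patient-level random effect so paired
#' region comparisons carry within-patient correlation.
#'
#' @param groups Tibble with columns `group`, `n`, `median_mM`, `iqr_lo`,
#'   `iqr_hi` (see [glioma_group_specs()]).
#' @param seed Integer seed.
#' @param missingness Named vector giving how many patients HAVE each
#'   optional compartment, e.g. `c(gdce = 22, necrosis = 9)`. Default
#'   `NULL` applies the study rates 22/28 and 9/28 scaled to the cohort
#'   size. Patients with necrosis are a subset of patients with gdce.
#' @param dist `"normal"` (default) or `"lognormal"` patient-level
#'   distribution for the whole-tumor median.
#' @param region_effect Fraction of region variance shared across a
#'   patient's regions (patient random effect), in `[0, 1)`.
#' @return A tibble, one row per patient: `id`, `group`, presence flags,
#'   per-region medians and volumes (mL, NA when absent), and
#'   `whole_tumor_median` (mM).
#' @export
simulate_cohort <- function(groups, seed,
                            missingness = NULL,
                            dist = c("normal", "lognormal"),
                            region_effect = 0.5) {
  dist <- match.arg(dist)
  stopifnot(is.data.frame(groups),
            all(c("group", "n", "median_mM", "iqr_lo", "iqr_hi") %in%
                  names(groups)),
            all(groups$n >= 1),
            all(groups$iqr_lo < groups$median_mM),
            all(groups$median_mM < groups$iqr_hi),
            region_effect >= 0, region_effect < 1)
  n_total <- sum(groups$n)
  miss <- missingness
  if (is.null(miss)) {
    # study-cohort rates: 22/28 patients with gdce, 9/28 with necrosis
    miss <- round(c(gdce = 22, necrosis = 9) / 28 * n_total)
  }
  if (any(miss > n_total) || miss[["necrosis"]] > miss[["gdce"]]) {
    stop("inconsistent compartment presence counts")
  }

  ref <- sodium_reference_values()
  withr::with_seed(seed, {
    wtm <- unlist(purrr::pmap(groups, function(group, n, median_mM,
                                               iqr_lo, iqr_hi, ...) {
      sdv <- iqr_to_sd(iqr_lo, iqr_hi)
      if (dist == "normal") {
        rtruncnorm_pos(n, median_mM, sdv)
      } else {
        # log-normal matched by median and IQR width
        sdlog <- (log(iqr_hi) - log(iqr_lo)) / 1.349
        stats::rlnorm(n, meanlog = log(median_mM), sdlog = sdlog)
      }
    }))
    grp <- rep(groups$group, groups$n)
    # compartment presence: necrotic patients are a subset of gdce patients
    has_gdce <- has_necrosis <- rep(FALSE, n_total)
    has_gdce[sample.int(n_total, miss[["gdce"]])] <- TRUE
    idx_g <- which(has_gdce)
    has_necrosis[idx_g[sample.int(length(idx_g),
                                  min(miss[["necrosis"]], length(idx_g)))]] <- TRUE
    # region medians: shared patient effect + region-specific residual
    b <- stats::rnorm(n_total)
    regmed <- vapply(seq_len(nrow(ref)), function(j) {
      z <- sqrt(region_effect) * b +
        sqrt(1 - region_effect) * stats::rnorm(n_total)
      pmax(ref$mean_mM[j] + ref$sd_mM[j] * z, 1)
    }, numeric(n_total))
    colnames(regmed) <- ref$region
    regmed[!has_gdce, "gdce"] <- NA_real_
    regmed[!has_necrosis, "necrosis"] <- NA_real_
    # region volumes (mL): log-normal around typical compartment sizes
    vol_mu <- c(nawm = 2, edema = 60, gdce = 15, necrosis = 4)
    vols <- vapply(names(vol_mu), function(r) {
      stats::rlnorm(n_total, meanlog = log(vol_mu[[r]]), sdlog = 0.5)
    }, numeric(n_total))
    vols[!has_gdce, "gdce"] <- NA_real_
    vols[!has_necrosis, "necrosis"] <- NA_real_
  })

  tibble::tibble(
    id = sprintf("P%03d", seq_len(n_total)),
    group = grp,
    has_gdce = has_gdce,
    has_necrosis = has_necrosis,
    nawm_median = regmed[, "nawm"],
    edema_median = regmed[, "edema"],
    gdce_median = regmed[, "gdce"],
    necrosis_median = regmed[, "necrosis"],
    nawm_volume_ml = vols[, "nawm"],
    edema_volume_ml = vols[, "edema"],
    gdce_volume_ml = vols[, "gdce"],
    necrosis_volume_ml = vols[, "necrosis"],
    whole_tumor_median = wtm
  )
}

#' Read / write a cohort table
#'
#' CSV round trip for the one-row-per-patient cohort schema produced by
#' [simulate_cohort()]. Reading validates that the required columns are
#' present and names any that are missing.
#'
#' @param path CSV path.
#' @param cohort Cohort tibble.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("id", "group", "whole_tumor_median")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}
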