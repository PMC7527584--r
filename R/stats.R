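#' Pairwise paired t-tests between tissue regions
#'
#' Two-sided paired t-tests on per-patient region medians, for every
#' unordered pair of regions, restricted per pair to patients possessing
#' both regions (pairwise-complete). The reported n therefore differs
#' between pairs when compartments are missing in part of the cohort
#' (e.g. necrosis pairs use only the necrotic patients).
#'
#' Degenerate pairs (zero variance of the differences) are flagged: if the
#' vectors are identical the test is reported as t = 0, p = 1; otherwise
#' the p-value is NA with `degenerate = TRUE`.
#'
#' @param cohort Cohort tibble with `<region>_median` columns (see
#'   [simulate_cohort()]).
#' @param regions Ordered region names; default nawm, edema, gdce,
#'   necrosis.
#' @return Tibble: `region_a`, `region_b`, `n`, `statistic`, `raw_p`,
#'   `degenerate`.
#' @export
paired_region_tests <- function(cohort,
                                regions = c("nawm", "edema", "gdce",
                                            "necrosis")) {
  cols <- paste0(regions, "_median")
  stopifnot(all(cols %in% names(cohort)))
  pairs <- utils::combn(seq_along(regions), 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- cohort[[cols[i]]]; b <- cohort[[cols[j]]]
    ok <- stats::complete.cases(a, b)
    n <- sum(ok)
    if (n < 2) {
      return(tibble::tibble(region_a = regions[i], region_b = regions[j],
                            n = n, statistic = NA_real_, raw_p = NA_real_,
                            degenerate = TRUE))
    }
    d <- a[ok] - b[ok]
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        return(tibble::tibble(region_a = regions[i], region_b = regions[j],
                              n = n, statistic = 0, raw_p = 1,
                              degenerate = FALSE))
      }
      return(tibble::tibble(region_a = regions[i], region_b = regions[j],
                            n = n, statistic = NA_real_, raw_p = NA_real_,
                            degenerate = TRUE))
    }
    tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
    tibble::tibble(region_a = regions[i], region_b = regions[j], n = n,
                   statistic = unname(tt$statistic), raw_p = tt$p.value,
                   degenerate = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Two-group comparison of sodium concentrations
#'
#' Mann-Whitney U test (rank sum with average ranks and tie-corrected
#' variance; exact null distribution when the combined sample size is at
#' most 20 and there are no ties, normal approximation otherwise) or a
#' two-sided unpaired t-test.
#'
#' @param values_a,values_b Numeric vectors (mM), both non-empty.
#' @param kind `"mann-whitney"` or `"unpaired-t"`.
#' @return Tibble: `test`, `n_a`, `n_b`, `statistic` (U or t), `raw_p`.
#' @export
group_test <- function(values_a, values_b,
                       kind = c("mann-whitney", "unpaired-t")) {
  kind <- match.arg(kind)
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (kind == "mann-whitney") {
    exact <- length(values_a) + length(values_b) <= 20
    wt <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = exact, correct = !exact)
    )
    tibble::tibble(test = "mann-whitney", n_a = length(values_a),
                   n_b = length(values_b),
                   statistic = unname(wt$statistic), raw_p = wt$p.value)
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    tibble::tibble(test = "unpaired-t", n_a = length(values_a),
                   n_b = length(values_b),
                   statistic = unname(tt$statistic), raw_p = tt$p.value)
  }
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the raw p-values ascending, multiplies the k-th smallest by
#' (m - k + 1), enforces monotonicity by a running maximum, caps at 1 and
#' returns the corrected values in the original order. `family_size` lets a
#' family be larger than the supplied vector (absent members treated as
#' p = 1, which never constrains the running maximum).
#'
#' @param raw_ps Raw p-values in `[0, 1]`.
#' @param family_size Family size m; default `length(raw_ps)`.
#' @return Corrected p-values, same order as the input.
#' @export
holm_correct <- function(raw_ps, family_size = length(raw_ps)) {
  if (any(!is.finite(raw_ps)) || any(raw_ps < 0) || any(raw_ps > 1)) {
    stop("raw p-values must lie in [0, 1]")
  }
  stopifnot(family_size >= length(raw_ps))
  stats::p.adjust(raw_ps, method = "holm", n = family_size)
}

# empirical AUC with positive class higher, via the rank form of the
# Mann-Whitney statistic (ties contribute 1/2)
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC analysis with Youden cut-off, DeLong CI and PR curve
#'
#' Builds the empirical ROC curve over midpoint thresholds (midpoints
#' between consecutive sorted unique values, plus sentinels below and above
#' all values), computes the trapezoidal AUC (identical to the normalized
#' Mann-Whitney U statistic; asserted internally), the DeLong 95% CI for
#' the AUC, the Youden-optimal cut-off with sensitivity and specificity and
#' their stratified-bootstrap percentile CIs, and the precision-recall
#' curve with its area (AUPRC).
#'
#' The positive class is taken to be the higher-valued one: sensitivity at
#' threshold t is the fraction of positives with value >= t.
#'
#' @param values Numeric scores (e.g. whole-tumor median sodium, mM).
#' @param labels Class labels, same length.
#' @param positive_class The label treated as positive (expected higher).
#' @param boot_n Bootstrap replicates for sensitivity/specificity CIs
#'   (default 2000); 0 disables bootstrap.
#' @param seed Seed for the bootstrap.
#' @param ci Compute the DeLong AUC CI (default TRUE).
#' @return An object of class `na_roc`.
#' @export
roc_analysis <- function(values, labels, positive_class, boot_n = 2000,
                         seed = 1L, ci = TRUE) {
  stopifnot(length(values) == length(labels))
  is_pos <- labels == positive_class
  pos <- values[is_pos]; neg <- values[!is_pos]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present for ROC analysis")
  }
  uq <- sort(unique(values))
  thr <- c(uq[1] - 1, (uq[-1] + uq[-length(uq)]) / 2, uq[length(uq)] + 1)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  auc <- auc_rank(pos, neg)
  # trapezoid over the empirical curve must agree with the rank form
  o <- order(1 - spec, sens)
  xs <- c(0, (1 - spec)[o], 1); ys <- c(0, sens[o], 1)
  auc_trap <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  stopifnot(abs(auc_trap - auc) < 1e-8)
  j <- sens + spec - 1
  best <- which.max(j)
  youden_cutoff <- thr[best]

  auc_ci <- c(NA_real_, NA_real_)
  if (ci) {
    resp <- factor(ifelse(is_pos, "pos", "neg"), levels = c("neg", "pos"))
    proc_ci <- suppressWarnings(suppressMessages(
      pROC::ci.auc(resp, values, direction = "<", method = "delong",
                   quiet = TRUE)
    ))
    auc_ci <- c(proc_ci[1], proc_ci[3])
  }

  sens_ci <- spec_ci <- c(NA_real_, NA_real_)
  if (boot_n > 0) {
    bs <- withr::with_seed(seed, {
      t(vapply(seq_len(boot_n), function(i) {
        p <- sample(pos, replace = TRUE)
        n <- sample(neg, replace = TRUE)
        c(mean(p >= youden_cutoff), mean(n < youden_cutoff))
      }, numeric(2)))
    })
    sens_ci <- unname(stats::quantile(bs[, 1], c(0.025, 0.975)))
    spec_ci <- unname(stats::quantile(bs[, 2], c(0.025, 0.975)))
  }

  # precision-recall over the same thresholds, descending so recall grows;
  # area by the average-precision estimator sum((R_i - R_{i-1}) * P_i)
  n_pos <- length(pos)
  thr_desc <- sort(thr, decreasing = TRUE)
  tp <- vapply(thr_desc, function(t) sum(pos >= t), numeric(1))
  fp <- vapply(thr_desc, function(t) sum(neg >= t), numeric(1))
  rec_s <- tp / n_pos
  prec_s <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  auprc <- sum(diff(c(0, rec_s)) * prec_s)

  structure(
    list(positive_class = positive_class,
         n_pos = length(pos), n_neg = length(neg),
         thresholds = thr, sensitivities = sens, specificities = spec,
         auc = auc, auc_ci_95 = auc_ci,
         youden_cutoff = youden_cutoff, youden_j = j[best],
         sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
         sens_ci_95 = sens_ci, spec_ci_95 = spec_ci,
         pr_recall = rec_s, pr_precision = prec_s, auprc = auprc),
    class = "na_roc"
  )
}

#' @export
print.na_roc <- function(x, ...) {
  cat(sprintf("<na_roc> positive = '%s' (n=%d vs n=%d)\n",
              x$positive_class, x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), AUPRC %.3f\n",
              x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$auprc))
  cat(sprintf("  Youden cut-off %.2f: sens %.2f (%.2f-%.2f), spec %.2f (%.2f-%.2f)\n",
              x$youden_cutoff, x$sens_at_cutoff, x$sens_ci_95[1],
              x$sens_ci_95[2], x$spec_at_cutoff, x$spec_ci_95[1],
              x$spec_ci_95[2]))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x A `na_roc` object.
#' @param ... Unused.
#' @export
tidy.na_roc <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds,
                 sensitivity = x$sensitivities,
                 specificity = x$specificities)
}

#' @rdname roc_analysis
#' @export
glance.na_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_lo = x$auc_ci_95[1], auc_hi = x$auc_ci_95[2],
    youden_cutoff = x$youden_cutoff, youden_j = x$youden_j,
    sensitivity = x$sens_at_cutoff, sens_lo = x$sens_ci_95[1],
    sens_hi = x$sens_ci_95[2],
    specificity = x$spec_at_cutoff, spec_lo = x$spec_ci_95[1],
    spec_hi = x$spec_ci_95[2],
    auprc = x$auprc, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname roc_analysis
#' @param object A `na_roc` object.
#' @export
autoplot.na_roc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::annotate("point", x = 1 - object$spec_at_cutoff,
                      y = object$sens_at_cutoff, colour = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.2f, Youden cut-off = %.2f",
                                  object$auc, object$youden_cutoff)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Correlation between compartment volume and sodium concentration
#'
#' Pearson correlation (two-sided) between a compartment's volume and its
#' median sodium concentration across patients.
#'
#' @param cohort Cohort tibble with `<region>_median` and
#'   `<region>_volume_ml` columns.
#' @param region Region name.
#' @return Tibble: `region`, `n`, `r`, `raw_p`, `degenerate`.
#' @export
volume_concentration_correlation <- function(cohort, region) {
  v <- cohort[[paste0(region, "_volume_ml")]]
  m <- cohort[[paste0(region, "_median")]]
  ok <- stats::complete.cases(v, m)
  if (sum(ok) < 3) stop("need at least 3 patients with region '", region, "'")
  if (stats::sd(v[ok]) == 0 || stats::sd(m[ok]) == 0) {
    return(tibble::tibble(region = region, n = sum(ok), r = NA_real_,
                          raw_p = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(v[ok], m[ok])
  tibble::tibble(region = region, n = sum(ok), r = unname(ct$estimate),
                 raw_p = ct$p.value, degenerate = FALSE)
}

#' Run the full cohort statistical battery
#'
#' Paired region t-tests, the three biomarker Mann-Whitney comparisons
#' (grade, IDH, MGMT), the recurrence t-test, and a single Holm family over
#' all raw p-values, mirroring the convention of correcting every reported
#' test to one global alpha.
#'
#' @param cohort Cohort tibble with a `group` column covering the
#'   comparisons of interest and region median columns.
#' @param comparisons Named list of character pairs
#'   `c(negative_group, positive_group)` for Mann-Whitney comparisons on
#'   `whole_tumor_median` (positive = expected-higher class).
#' @param t_comparisons Like `comparisons` but tested with the unpaired
#'   t-test.
#' @return Tibble of test results with Holm-corrected p-values
#'   (`corrected_p`) over one family.
#' @export
cohort_statistics <- function(cohort, comparisons = list(), t_comparisons = list()) {
  paired <- paired_region_tests(cohort) |>
    dplyr::mutate(test = "paired-t",
                  contrast = paste(.data$region_a, "vs", .data$region_b)) |>
    dplyr::select("test", "contrast", "n", "statistic", "raw_p")
  two_group <- function(cmp, kind) {
    purrr::imap(cmp, function(pair, nm) {
      a <- cohort$whole_tumor_median[cohort$group == pair[1]]
      b <- cohort$whole_tumor_median[cohort$group == pair[2]]
      group_test(a, b, kind = kind) |>
        dplyr::mutate(contrast = nm, n = .data$n_a + .data$n_b) |>
        dplyr::select("test", "contrast", "n", "statistic", "raw_p")
    }) |> dplyr::bind_rows()
  }
  res <- dplyr::bind_rows(paired,
                          two_group(comparisons, "mann-whitney"),
                          two_group(t_comparisons, "unpaired-t"))
  ok <- !is.na(res$raw_p)
  res$corrected_p <- NA_real_
  res$corrected_p[ok] <- holm_correct(res$raw_p[ok])
  res
}
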