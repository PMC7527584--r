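# brute-force Mann-Whitney U and its exact two-sided p by enumeration
brute_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}
brute_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  obs <- brute_u(a, b)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) brute_u(pooled[ix], pooled[-ix]))
  mu <- n1 * (length(b)) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

test_that("paired region tests use pairwise-complete patients", {
  co <- simulate_cohort(glioma_group_specs()[1:2, ], seed = 4)
  res <- paired_region_tests(co)
  expect_equal(nrow(res), 6)
  nec <- res[res$region_a == "nawm" & res$region_b == "necrosis", ]
  expect_equal(nec$n, 9)
  gd <- res[res$region_a == "nawm" & res$region_b == "gdce", ]
  expect_equal(gd$n, 22)
  expect_true(all(res$raw_p >= 0 & res$raw_p <= 1))
  # with correlated compartments the tissue contrasts are significant
  expect_lt(res$raw_p[res$region_a == "nawm" & res$region_b == "edema"], 0.01)
})

test_that("degenerate paired inputs are flagged, identical ones give p = 1", {
  co <- tibble::tibble(nawm_median = c(1, 2, 3), edema_median = c(1, 2, 3),
                       gdce_median = c(2, 3, 4), necrosis_median = NA_real_)
  res <- paired_region_tests(co)
  id <- res[res$region_a == "nawm" & res$region_b == "edema", ]
  expect_equal(id$statistic, 0); expect_equal(id$raw_p, 1)
  sh <- res[res$region_a == "nawm" & res$region_b == "gdce", ]
  expect_true(sh$degenerate)
  expect_true(is.na(sh$raw_p))
  nec <- res[res$region_b == "necrosis", ]
  expect_true(all(nec$degenerate))
})

test_that("Mann-Whitney matches brute-force enumeration on small samples", {
  gt <- group_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(gt$statistic, 0)
  expect_equal(gt$raw_p, 0.1)
  expect_equal(gt$raw_p, brute_exact_p(c(1, 2, 3), c(10, 11, 12)))
  # identical groups: exact symmetric p = 1
  expect_equal(group_test(1:4, 1:4)$raw_p, 1)
  expect_error(group_test(numeric(0), 1:3), "non-empty")
  # random instances: U statistic agrees with the brute-force definition
  for (s in 1:10) {
    ab <- withr::with_seed(s, list(a = round(runif(4), 2),
                                   b = round(runif(5), 2)))
    expect_equal(group_test(ab$a, ab$b)$statistic, brute_u(ab$a, ab$b))
  }
})

test_that("grade comparison is well powered at the published effect size", {
  gs <- glioma_group_specs()
  sig <- vapply(1:200, function(s) {
    co <- simulate_cohort(gs[gs$comparison == "grade", ], seed = 30000 + s)
    gt <- group_test(co$whole_tumor_median[co$group == "gbm"],
                     co$whole_tumor_median[co$group == "non_gbm"])
    gt$raw_p < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("Holm step-down reproduces the published correction family", {
  raw <- c(5.2e-10, 2.7e-9, 4.6e-5, 6.7e-6, 4.3e-4, 0.0078,
           0.0012, 0.0094, 0.5395, 0.5022, 0.8916)
  corr <- holm_correct(raw)
  expect_equal(corr[6], 0.039)             # gdce vs necrosis
  expect_equal(corr[5], 0.003, tolerance = 1e-2)  # edema vs necrosis
  expect_equal(round(corr[5], 5), 0.00301)
  expect_equal(corr[1], 5.72e-9, tolerance = 1e-3)
  expect_equal(corr[9], 1); expect_equal(corr[10], 1); expect_equal(corr[11], 1)
  # single test is unchanged
  expect_equal(holm_correct(0.04), 0.04)
  expect_error(holm_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm correction obeys its dominance bounds on random families", {
  for (s in 1:20) {
    p <- withr::with_seed(s, runif(sample(1:12, 1)))
    m <- length(p)
    cp <- holm_correct(p)
    expect_true(all(cp >= p))
    expect_true(all(cp <= pmin(1, m * p) + 1e-12))
    expect_true(all(cp <= 1))
    # monotone in the sorted order
    expect_true(all(diff(cp[order(p)]) >= -1e-12))
  }
})

test_that("ROC analysis handles perfect separation and reports midpoints", {
  r <- roc_analysis(c(1, 2, 3, 10, 11), c("n", "n", "n", "p", "p"), "p",
                    boot_n = 100, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$youden_cutoff, 6.5)
  expect_equal(r$sens_at_cutoff, 1)
  expect_equal(r$spec_at_cutoff, 1)
  expect_equal(r$auprc, 1)
  expect_true(r$auc_ci_95[1] <= 1 && r$auc_ci_95[2] == 1)
  # curve endpoints
  td <- tidy(r)
  expect_true(any(td$sensitivity == 1 & td$specificity == 0))
  expect_true(any(td$sensitivity == 0 & td$specificity == 1))
})

test_that("AUC equals the normalized U statistic on random instances", {
  for (s in 1:50) {
    d <- withr::with_seed(s, {
      n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
      list(pos = sample(1:8, n1, replace = TRUE),   # ties on purpose
           neg = sample(1:8, n2, replace = TRUE))
    })
    r <- roc_analysis(c(d$pos, d$neg),
                      rep(c("p", "n"), c(length(d$pos), length(d$neg))),
                      "p", boot_n = 0, ci = FALSE)
    expect_equal(r$auc,
                 brute_u(d$pos, d$neg) / (length(d$pos) * length(d$neg)))
  }
})

test_that("AUC and Youden J are invariant under monotone transforms", {
  d <- withr::with_seed(99, list(v = rnorm(30), g = rep(c("p", "n"), 15)))
  base <- roc_analysis(d$v, d$g, "p", boot_n = 0, ci = FALSE)
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3)) {
    tr <- roc_analysis(f(d$v), d$g, "p", boot_n = 0, ci = FALSE)
    expect_equal(tr$auc, base$auc)
    expect_equal(tr$youden_j, base$youden_j)
  }
})

test_that("AUC is 0.5 on average when labels are independent of values", {
  aucs <- vapply(1:1000, function(s) {
    d <- withr::with_seed(40000 + s, {
      list(v = rnorm(28), g = sample(rep(c("p", "n"), c(7, 21))))
    })
    roc_analysis(d$v, d$g, "p", boot_n = 0, ci = FALSE)$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.04)
})

test_that("AUC agrees with the independent pROC implementation", {
  d <- withr::with_seed(7, list(v = rnorm(28),
                                g = rep(c("p", "n"), c(7, 21))))
  r <- roc_analysis(d$v, d$g, "p", boot_n = 0, ci = FALSE)
  pr <- suppressMessages(pROC::auc(
    factor(d$g, levels = c("n", "p")), d$v, direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(pr))
})

test_that("volume-concentration correlation matches its closed cases", {
  co <- tibble::tibble(gdce_volume_ml = c(1, 2, 3, 4),
                       gdce_median = c(10, 20, 30, 40))
  expect_equal(volume_concentration_correlation(co, "gdce")$r, 1)
  co$gdce_median <- rev(co$gdce_median)
  expect_equal(volume_concentration_correlation(co, "gdce")$r, -1)
  co$gdce_median <- c(5, 5, 5, 5)
  expect_true(volume_concentration_correlation(co, "gdce")$degenerate)
  expect_error(volume_concentration_correlation(co[1:2, ], "gdce"),
               "at least 3")
  # null simulation: independent draws have mean r near 0
  rs <- vapply(1:500, function(s) {
    d <- withr::with_seed(50000 + s,
                          tibble::tibble(gdce_volume_ml = rnorm(28),
                                         gdce_median = rnorm(28)))
    volume_concentration_correlation(d, "gdce")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("the cohort battery corrects one family and keeps dominance", {
  gs <- glioma_group_specs()
  co <- simulate_cohort(gs[gs$comparison == "grade", ], seed = 77)
  res <- cohort_statistics(
    co, comparisons = list(grade = c("gbm", "non_gbm")))
  expect_equal(nrow(res), 7)  # 6 paired + 1 group test
  ok <- !is.na(res$raw_p)
  expect_true(all(res$corrected_p[ok] >= res$raw_p[ok]))
  expect_true(all(res$corrected_p[ok] <= 1))
})
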