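test_that("nawm slice ROIs merge by voxel union", {
  n <- c(12, 12, 6)
  roi <- function(zs, xs = 1:5, ys = 1:4) {
    m <- array(FALSE, n); m[xs, ys, zs] <- TRUE; m
  }
  merged <- merge_nawm(list(roi(1), roi(2), roi(3)))
  expect_equal(sum(region_mask(merged, "nawm")), 60)
  # duplicates count once
  dup <- merge_nawm(list(roi(1), roi(1)))
  expect_equal(sum(region_mask(dup, "nawm")), 20)
  expect_error(merge_nawm(list()), "at least one")
})

test_that("segmentation composition repairs overlap and guards nawm", {
  n <- c(10, 10, 10)
  box <- function(xs) { m <- array(FALSE, n); m[xs, 1:6, 1:6] <- TRUE; m }
  edema <- box(1:6); gdce <- box(3:5); necrosis <- box(4:4)
  expect_message(
    seg <- build_segmentation(edema, gdce, necrosis, voxel_mm = 3),
    "precedence"
  )
  # innermost wins
  expect_equal(sum(region_mask(seg, "necrosis")), sum(necrosis))
  expect_equal(sum(region_mask(seg, "gdce")), sum(gdce) - sum(necrosis))
  expect_equal(sum(region_mask(seg, "edema")), sum(edema) - sum(gdce))
  # nawm ROI inside tumor is rejected
  expect_error(build_segmentation(edema, nawm = box(2:2)), "overlaps")
})

test_that("whole-tumor fusion is union minus necrosis and cavity", {
  n <- c(10, 10, 10)
  box <- function(xs) { m <- array(FALSE, n); m[xs, 1:6, 1:6] <- TRUE; m }
  seg <- suppressMessages(
    build_segmentation(box(1:6), box(5:8), box(6:6), cavity = box(9:9))
  )
  wt <- whole_tumor(seg)
  m <- region_mask(wt, "whole_tumor")
  manual <- (box(1:6) | box(5:8)) & !box(6:6) & !box(9:9)
  expect_equal(m, manual)
  # edema-only patients: whole tumor equals edema
  seg2 <- build_segmentation(box(1:6))
  expect_equal(sum(region_mask(whole_tumor(seg2), "whole_tumor")),
               sum(box(1:6)))
  # empty result is rejected
  seg3 <- suppressMessages(build_segmentation(box(3:4), necrosis = box(3:4)))
  expect_error(whole_tumor(seg3), "empty")
})

test_that("region statistics match hand arithmetic and flag absence", {
  lab <- na_labels(array(c(1L, 1L, 1L, 0L), c(4, 1, 1)), 3,
                   c(air = 0L, nawm = 1L))
  conc <- na_volume(array(c(1, 2, 100, 0), c(4, 1, 1)), 3, "mM")
  rs <- region_stats(conc, lab)
  expect_equal(rs$median, 2)
  expect_equal(rs$mean, 34.33, tolerance = 1e-3)
  expect_equal(rs$volume_ml, 3 * 27 / 1000)
  # constant region
  conc2 <- na_volume(array(50, c(4, 1, 1)), 3, "mM")
  rs2 <- region_stats(conc2, lab)
  expect_equal(rs2$mean, 50); expect_equal(rs2$median, 50)
  expect_equal(rs2$sd, 0)
  # absent regions are omitted rather than reported as zero
  lab2 <- na_labels(array(0L, c(4, 1, 1)), 3, c(air = 0L, nawm = 1L))
  expect_equal(nrow(region_stats(conc, lab2)), 0)
  # unit enforcement at the stage boundary
  au <- na_volume(array(1, c(4, 1, 1)), 3, "a.u.")
  expect_error(region_stats(au, lab), "mM")
})

test_that("normalization to nawm gives dimensionless ratios", {
  rs <- tibble::tibble(region = c("nawm", "necrosis", "empty"),
                       n_voxels = c(10, 10, 10), volume_ml = 1,
                       mean = c(37.84, 81.88, 0), sd = 1,
                       median = c(37, 80, 0))
  out <- normalize_to_nawm(rs)
  expect_equal(out$mean_norm[1], 1)
  expect_equal(out$mean_norm[2], 2.164, tolerance = 1e-3)
  expect_equal(out$mean_norm[3], 0)
  rs$mean[1] <- 0
  expect_error(normalize_to_nawm(rs), "positive")
})

test_that("mask resampling is identity on the same grid and conserves volume", {
  p <- generate_phantom(small_spec())
  same <- resample_mask(p$labels, p$truth)
  expect_identical(same$data, p$labels$data)
  # solid cube on a 1.5 mm grid downsampled 2x to the 3 mm grid
  fine <- array(0L, c(32, 32, 32))
  fine[5:24, 5:24, 5:24] <- 1L
  fine_lab <- na_labels(fine, 1.5, c(air = 0L, nawm = 1L))
  coarse <- na_volume(array(0, c(16, 16, 16)), 3, "a.u.")
  out <- resample_mask(fine_lab, coarse)
  v_fine <- sum(fine == 1L) * 1.5^3
  v_coarse <- sum(out$data == 1L) * 3^3
  # conservation within one surface-voxel shell of the coarse grid
  surface <- 6 * 10^2 + 12 * 10 + 8  # coarse surface voxel count bound
  expect_lt(abs(v_coarse - v_fine), surface * 27)
  # single fine voxel may vanish on the coarse grid, with a warning
  tiny <- array(0L, c(32, 32, 32)); tiny[6, 6, 6] <- 1L
  tiny_lab <- na_labels(tiny, 1.5, c(air = 0L, nawm = 1L))
  out2 <- withCallingHandlers(
    resample_mask(tiny_lab, coarse),
    warning = function(w) invokeRestart("muffleWarning")
  )
  expect_lte(sum(out2$data), 1)
})

test_that("whole-tumor median equals the pooled voxel median", {
  p <- generate_phantom(small_spec())
  sigma <- sigma_for_snr(p$truth, p$labels, snr = 20)
  sim <- simulate_signal(p$truth, sigma = sigma, seed = 9)
  q <- quantify_sodium(sim$S_alpha, sim$S_2alpha, p$labels,
                       snr_floor = 2 * sigma)
  wt <- whole_tumor(p$labels)
  rs <- region_stats(q$concentration, wt)
  pooled <- q$concentration$data[region_mask(p$labels, "edema") |
                                   region_mask(p$labels, "gdce")]
  expect_equal(rs$median, median(pooled))
  # volume additivity |A u B| = |A| + |B| - |A n B| (disjoint here)
  expect_equal(rs$n_voxels,
               sum(region_mask(p$labels, "edema")) +
                 sum(region_mask(p$labels, "gdce")))
})
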