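test_that("roi_stats agrees with direct arithmetic", {
  m <- array(NaN, c(4, 4, 1))
  lab <- array(0L, c(4, 4, 1))
  m[1:3, 1, 1] <- c(900, 1000, 1100); lab[1:3, 1, 1] <- 1L
  m[1:2, 2, 1] <- 1000; lab[1:2, 2, 1] <- 2L
  st <- roi_stats(m, lab)
  expect_equal(st$mean_t1_ms[st$label == 1], 1000)
  expect_equal(st$sd_t1_ms[st$label == 1], 100)  # sample SD, n - 1
  expect_equal(st$sd_t1_ms[st$label == 2], 0)
  # a label with no valid voxels is excluded with a warning
  lab[4, 4, 1] <- 7L
  expect_warning(st2 <- roi_stats(m, lab), "label 7")
  expect_false(7 %in% st2$label)
  # bias against ground truth
  truth <- array(0, c(4, 4, 1)); truth[lab == 1L] <- 950
  stt <- suppressWarnings(roi_stats(m, lab, truth))
  expect_equal(stt$bias_ms[stt$label == 1], 50)
  expect_error(roi_stats(m, array(0L, c(2, 2, 1))), "shape")
})

test_that("bland_altman reproduces hand-computed bias and limits", {
  ba <- bland_altman(c(10, 20), c(20, 10))  # diffs {-10, +10}
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(200), tolerance = 1e-12)  # ~14.14
  expect_equal(ba$loa_upper, 1.96 * sqrt(200), tolerance = 1e-12)  # ~27.7
  expect_equal(ba$loa_upper + ba$loa_lower, 2 * ba$bias)  # symmetric limits

  a <- c(1000, 1100, 1250)
  ident <- bland_altman(a, a)
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa_lower, 0)
  offs <- bland_altman(a + 50, a)  # pure systematic difference
  expect_equal(offs$bias, 50)
  expect_equal(offs$sd_diff, 0)
  # antisymmetry under argument swap
  ba1 <- bland_altman(a, rev(a)); ba2 <- bland_altman(rev(a), a)
  expect_equal(ba1$bias, -ba2$bias)
  expect_error(bland_altman(1:3, 1:2), "equal length")
  expect_error(bland_altman(1, 2), "at least 2")
})

# shared annulus fixture for the AHA checks
aha_fixture <- function(t1_myo = 1100, t1_blood = 1700) {
  spec <- cardiac_phantom_spec(grid_shape = c(32, 32, 6),
                               spacing_mm = c(1.4, 1.4, 8),
                               t1_myo_ms = t1_myo, t1_blood_ms = t1_blood,
                               noise_sigma = 0)
  gt <- build_phantom(spec)
  list(gt = gt, t1 = gt$t1_ms, myo = gt$label == 1L, blood = gt$label == 2L,
       center = spec$grid_shape[1:2] * spec$spacing_mm[1:2] / 2,
       part = list(base = 1:2, mid = 3:4, apex = 5:6))
}

test_that("uniform annulus reports the same value in all 16 segments", {
  fx <- aha_fixture()
  aha <- aha_segments(fx$t1, fx$myo, fx$blood, fx$center,
                      rv_insertion_angle_deg = 90, slice_partition = fx$part,
                      spacing_mm = c(1.4, 1.4, 8))
  expect_identical(nrow(aha), 17L)
  expect_true(all(aha$mean_t1_ms[1:16] == 1100))
  expect_true(all(aha$sd_t1_ms[1:16] == 0, na.rm = TRUE))
  expect_equal(aha$mean_t1_ms[17], 1700)  # blood pool in the center segment
  expect_true(all(aha$n_voxels[1:16] > 0))
})

test_that("segments partition the myocardium mask within declared slices", {
  fx <- aha_fixture()
  aha <- aha_segments(fx$t1, fx$myo, fx$blood, fx$center,
                      slice_partition = fx$part, spacing_mm = c(1.4, 1.4, 8))
  seg <- attr(aha, "segment_labels")
  expect_true(all(seg[fx$myo] > 0))          # union covers the mask
  expect_true(all(seg[!fx$myo] == 0))        # nothing outside it
  expect_identical(sum(aha$n_voxels[1:16]), sum(fx$myo))  # pairwise disjoint
  # ring sizes: 6 + 6 basal/mid segments, 4 apical
  expect_setequal(unique(seg[, , 1:4][fx$myo[, , 1:4]]), 1:12)
  expect_setequal(unique(seg[, , 5:6][fx$myo[, , 5:6]]), 13:16)
})

test_that("a 60-degree sector lands in exactly one basal segment", {
  fx <- aha_fixture()
  t1 <- fx$t1
  # paint the first basal segment's sector (90..150 deg ccw from +x) to 1300
  cx <- t1forge:::voxel_centers(32, 1.4) - fx$center[1]
  cy <- t1forge:::voxel_centers(32, 1.4) - fx$center[2]
  xx <- matrix(cx, 32, 32)               # x varies along rows
  yy <- matrix(cy, 32, 32, byrow = TRUE) # y varies along columns
  ang <- (atan2(yy, xx) * 180 / pi - 90) %% 360
  sector <- ang >= 0 & ang < 60
  for (z in 1:2) {
    sl <- t1[, , z]; sl[sector & fx$myo[, , z]] <- 1300; t1[, , z] <- sl
  }
  aha <- aha_segments(t1, fx$myo, fx$blood, fx$center,
                      rv_insertion_angle_deg = 90, slice_partition = fx$part,
                      spacing_mm = c(1.4, 1.4, 8))
  expect_equal(aha$mean_t1_ms[1], 1300)
  expect_true(all(aha$mean_t1_ms[2:6] == 1100))
})

test_that("empty myocardium in a declared slice range is an error", {
  fx <- aha_fixture()
  myo <- fx$myo; myo[, , 5:6] <- FALSE
  expect_error(aha_segments(fx$t1, myo, fx$blood, fx$center,
                            slice_partition = fx$part,
                            spacing_mm = c(1.4, 1.4, 8)), "apex")
  expect_error(aha_segments(fx$t1, fx$myo, fx$blood, fx$center,
                            slice_partition = list(base = 1:3, mid = 3:4,
                                                   apex = 5:6)),
               "disjoint")
})
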