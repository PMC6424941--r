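ts9 <- c(seq(100, 700, length.out = 8), Inf)
gen_signals <- function(a, b, t1, times = ts9) {
  e <- exp(-times / t1)
  e[!is.finite(times)] <- 0
  a * (1 - b * e)
}

test_that("noiseless three-parameter curves are inverted exactly", {
  cases <- list(c(1000, 1, 1000), c(1000, 0.95, 1000), c(500, 0.9, 250),
                c(2000, 1.05, 1500), c(800, 0.85, 612.37))
  for (cs in cases) {
    f <- fit_voxel(gen_signals(cs[1], cs[2], cs[3]), ts9)
    expect_true(f$converged)
    expect_lt(abs(f$t1_ms - cs[3]) / cs[3], 1e-3)
    expect_lt(abs(f$a - cs[1]) / cs[1], 1e-3)
    expect_lt(abs(f$b - cs[2]) / cs[2], 1e-3)
    expect_lt(f$residual, 1e-4 * cs[1])
  }
})

test_that("degenerate voxels are flagged invalid, not raised", {
  f <- fit_voxel(rep(0, 9), ts9)
  expect_false(f$converged)
  expect_true(is.nan(f$t1_ms))
  # flat positive curve: B -> 0, T1 unidentifiable
  f <- fit_voxel(rep(750, 9), ts9)
  expect_false(f$converged)
  f <- fit_voxel(c(NA, gen_signals(1000, 1, 800)[-1]), ts9)
  expect_false(f$converged)
  expect_error(fit_voxel(1:3, c(100, 200, Inf)), "at least 4")
})

test_that("fit is scale-equivariant and permutation-invariant", {
  s <- gen_signals(1000, 0.93, 700)
  f1 <- fit_voxel(s, ts9)
  f2 <- fit_voxel(5 * s, ts9)
  expect_equal(f2$a, 5 * f1$a, tolerance = 1e-6)
  expect_equal(f2$t1_ms, f1$t1_ms, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
  perm <- c(9, 3, 1, 5, 2, 8, 4, 7, 6)
  f3 <- fit_voxel(s[perm], ts9[perm])
  expect_equal(f3$t1_ms, f1$t1_ms, tolerance = 1e-8)
})

test_that("map fitting recovers every vial of the noiseless phantom", {
  spec <- small_vial_spec(noise_sigma = 0)
  gt <- build_phantom(spec)
  stk <- simulate_stack(gt, spec)
  res <- fit_t1_map(stk, mask = gt$label > 0)
  st <- roi_stats(res, gt$label, gt)
  expect_identical(nrow(st), 9L)
  expect_true(all(abs(st$bias_ms) / st$truth_t1_ms < 1e-3))
  expect_true(all(res$valid[gt$label > 0]))
  expect_true(all(is.nan(res$t1_ms[gt$label == 0])))
})

test_that("empty masks and mask mismatches are handled", {
  stk <- tiny_stack(c(4, 4, 2), n = 4, seed = 2)
  res <- fit_t1_map(stk, mask = array(FALSE, c(4, 4, 2)))
  expect_identical(sum(res$valid), 0L)
  expect_error(fit_t1_map(stk, mask = array(TRUE, c(3, 4, 2))), "mask shape")
})

test_that("denoising tightens the fitted T1 spread on noisy data", {
  spec <- small_vial_spec(noise_sigma = 10, seed = 21L)
  gt <- build_phantom(spec)
  stk <- simulate_stack(gt, spec)
  roi <- t1forge:::erode_labels(gt$label, 1L)
  mask <- roi > 0
  raw <- roi_stats(fit_t1_map(stk, mask), roi, gt)
  den <- roi_stats(fit_t1_map(denoise_stack(stk)$stack, mask), roi, gt)
  expect_true(all(raw$sd_t1_ms > 0))
  expect_lt(mean(den$sd_t1_ms), mean(raw$sd_t1_ms))
})
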