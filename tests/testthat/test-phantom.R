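test_that("rasterization fills the grid consistently with the region list", {
  spec <- phantom_spec(
    grid_shape = c(8, 8, 4), spacing_mm = c(1, 1, 2),
    regions = list(list(label = 3L, shape = "box", min_mm = c(0, 0, 0),
                        max_mm = c(100, 100, 100), t1_ms = 1000, a = 1)),
    times_ms = c(100, 400, Inf))
  gt <- build_phantom(spec)
  expect_true(all(gt$label == 3L))
  expect_true(all(gt$t1_ms == 1000))
  expect_true(all(gt$a == 1))
})

test_that("nine disjoint vials give ten labels spanning 250-1500 ms", {
  gt <- build_phantom(vial_phantom_spec())
  labs <- sort(unique(as.vector(gt$label)))
  expect_identical(labs, 0:9)
  t1s <- sort(unique(gt$t1_ms[gt$label > 0]))
  expect_length(t1s, 9L)
  expect_equal(range(t1s), c(250, 1500), tolerance = 1e-10)
  # background carries no signal
  expect_true(all(gt$t1_ms[gt$label == 0] == 0))
  expect_true(all(gt$a[gt$label == 0] == 0))
})

test_that("degenerate and colliding geometry are handled as declared", {
  base <- list(label = 1L, shape = "cylinder", center_mm = c(4, 4),
               radius_mm = 3, t1_ms = 500, a = 1)
  mk <- function(regions) phantom_spec(c(8, 8, 2), c(1, 1, 1), regions,
                                       times_ms = c(100, Inf))
  expect_warning(build_phantom(mk(list(modifyList(base, list(radius_mm = 0))))),
                 "zero voxels")
  overlap <- modifyList(base, list(label = 2L, radius_mm = 2))
  expect_error(build_phantom(mk(list(base, overlap))), "overlaps region\\(s\\) 1")
  ov <- modifyList(overlap, list(override = TRUE))
  gt <- build_phantom(mk(list(base, ov)))
  expect_setequal(unique(as.vector(gt$label)), c(0L, 1L, 2L))
})

test_that("noiseless signals follow the saturation-recovery curve", {
  expect_equal(sr_signal(1000, 1000, 1000), 1000 * (1 - exp(-1)),
               tolerance = 1e-12)
  spec <- phantom_spec(
    c(4, 4, 2), c(1, 1, 1),
    list(list(label = 1L, shape = "box", min_mm = c(0, 0, 0),
              max_mm = c(10, 10, 10), t1_ms = 800, a = 500)),
    times_ms = c(100, 300, 700, Inf), noise_sigma = 0)
  stk <- simulate_stack(build_phantom(spec), spec)
  expect_equal(stk$data[1, 1, 1, 4], 500)  # unprepared image is exactly A
  expect_equal(stk$data[2, 3, 1, 1], 500 * (1 - exp(-100 / 800)),
               tolerance = 1e-12)
  # monotone recovery: strictly increasing in TS wherever A > 0
  d <- stk$data
  expect_true(all(d[, , , 2] > d[, , , 1]))
  expect_true(all(d[, , , 3] > d[, , , 2]))
  expect_true(all(d[, , , 4] > d[, , , 3]))
})

test_that("noise models behave as configured and reproducibly", {
  spec <- phantom_spec(
    c(30, 30, 12), c(1, 1, 1),
    list(list(label = 1L, shape = "box", min_mm = c(0, 0, 0),
              max_mm = c(1e3, 1e3, 1e3), t1_ms = 1000, a = 1000)),
    times_ms = c(100, Inf), noise_sigma = 20, seed = 11L)
  gt <- build_phantom(spec)
  s1 <- simulate_stack(gt, spec)
  s2 <- simulate_stack(gt, spec)
  expect_identical(s1$data, s2$data)  # bit-identical under one seed
  # law of large numbers: sample SD of the unprepared image ~ sigma (5%)
  sdev <- sd(s1$data[, , , 2])
  expect_lt(abs(sdev - 20) / 20, 0.05)

  spec$noise_model <- "rician"
  sr <- simulate_stack(gt, spec)
  expect_true(all(sr$data >= 0))

  spec$noise_sigma <- -1
  expect_error(simulate_stack(gt, spec), "sigma")
})

test_that("phantom spec validation rejects bad schedules and geometry", {
  reg <- list(list(label = 1L, shape = "box", min_mm = c(0, 0, 0),
                   max_mm = c(1, 1, 1), t1_ms = 100, a = 1))
  expect_error(phantom_spec(c(4, 4, 1), c(1, 1, 1), reg,
                            times_ms = c(300, 100, Inf)), "increasing")
  expect_error(phantom_spec(c(4, 4, 1), c(1, 1, 1), reg,
                            times_ms = c(-5, 100)), "> 0")
  expect_error(phantom_spec(c(4, 4, 0), c(1, 1, 1), reg, c(100, Inf)),
               "grid_shape")
  expect_error(phantom_spec(c(4, 4, 1), c(1, 0, 1), reg, c(100, Inf)),
               "spacing")
})
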