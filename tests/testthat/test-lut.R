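geom <- eye_geometry()
cam <- camera_model()
lut <- build_calibration_lut(geom, cam, step = 0.01)

test_that("the default grid has (range/step) + 1 entries", {
  expect_equal(length(seq(-20, 20, by = 0.001)), 40001)
  expect_equal(length(lut$angle_grid), 4001)
  expect_equal(lut$d_cal, 4)
})

test_that("LUT center positions are strictly monotone", {
  expect_true(all(diff(lut$center_positions) > 0))
})

test_that("apparent_angle inverts the forward model on and between grid points", {
  # exact grid positions map to exact grid angles
  i <- c(1, 700, 2000, 4001)
  expect_equal(apparent_angle(lut, lut$center_positions[i]),
               lut$angle_grid[i], tolerance = 1e-12)
  # midpoints interpolate linearly
  mid_pos <- (lut$center_positions[100] + lut$center_positions[101]) / 2
  expect_equal(apparent_angle(lut, mid_pos),
               (lut$angle_grid[100] + lut$angle_grid[101]) / 2,
               tolerance = 1e-10)
  # round trip through fresh forward traces
  probes <- c(-17.3, -4.2, 0, 1.234, 9.99, 16)
  centers <- psatools:::.perceived_centers(geom, cam, probes, lut$d_cal)
  expect_equal(apparent_angle(lut, centers), probes,
               tolerance = lut$step)
})

test_that("apparent angles agree with an independent root-finding inverse", {
  set.seed(5)
  probes <- runif(8, min(lut$center_positions), max(lut$center_positions))
  for (u in probes) {
    # invert the forward model directly with uniroot on fresh traces
    th <- uniroot(function(a)
      psatools:::.perceived_centers(geom, cam, a, lut$d_cal) - u,
      lower = -20, upper = 20, tol = 1e-10)$root
    expect_lt(abs(apparent_angle(lut, u) - th), lut$step)
  }
})

test_that("coarse and fine LUTs agree to the coarse step", {
  fine <- build_calibration_lut(geom, cam, step = 0.002,
                                angle_min = -5, angle_max = 5)
  coarse <- build_calibration_lut(geom, cam, step = 0.1,
                                  angle_min = -5, angle_max = 5)
  set.seed(9)
  u <- runif(20, max(min(fine$center_positions), min(coarse$center_positions)),
             min(max(fine$center_positions), max(coarse$center_positions)))
  expect_lt(max(abs(apparent_angle(fine, u) - apparent_angle(coarse, u))),
            0.1)
})

test_that("out-of-range positions raise a range error", {
  expect_error(apparent_angle(lut, max(lut$center_positions) * 1.1),
               "outside the calibrated range")
})

test_that("invalid grid configurations are rejected", {
  expect_error(build_calibration_lut(geom, cam, step = 0),
               "step")
  expect_error(build_calibration_lut(geom, cam, angle_min = 5,
                                     angle_max = -5))
})
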