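geom <- eye_geometry()
cam <- camera_model()

test_that("frontal viewing gives mirror-symmetric edge rays", {
  st <- eye_state(geom, 0, 4)
  near <- trace_pupil_ray(st, cam, "near")
  far <- trace_pupil_ray(st, cam, "far")
  expect_equal(near$image_pos, -far$image_pos, tolerance = 1e-10)
  pc <- perceived_pupil_center(st, cam)
  expect_equal(pc$perceived_center, 0, tolerance = 1e-12)
  expect_equal(pc$perceived_center,
               (pc$far_ray_image_pos + pc$near_ray_image_pos) / 2)
})

test_that("solved corneal intersections satisfy Snell's law to 1e-10", {
  set.seed(11)
  for (i in 1:20) {
    st <- eye_state(geom, runif(1, -15, 15), runif(1, 2, 6))
    for (edge in c("near", "far")) {
      tr <- trace_pupil_ray(st, cam, edge)
      expect_false(tr$no_solution)
      expect_lt(abs(tr$snell_residual), 1e-10)
      expect_lt(abs(tr$miss), 1e-10)
    }
  }
})

test_that("solver agrees with the dense brute-force surface search", {
  set.seed(42)
  n <- 30
  th <- runif(n, -15, 15); d <- runif(n, 2, 6)
  side <- sample(c(-1, 1), n, replace = TRUE)
  solved <- psatools:::.solve_edge(geom, cam, th, d, side)
  for (i in seq_len(n)) {
    phi_bf <- brute_force_phi(geom, cam, th[i], d[i], side[i])
    expect_lt(abs(solved$phi[i] - phi_bf), 1e-6)
  }
})

test_that("brute-force agreement also holds for the elliptical cornea", {
  ell <- ellipsoidal_eye()
  set.seed(7)
  th <- runif(10, -12, 12); d <- runif(10, 2, 6)
  side <- sample(c(-1, 1), 10, replace = TRUE)
  solved <- psatools:::.solve_edge(ell, cam, th, d, side)
  for (i in 1:10) {
    expect_lt(abs(solved$phi[i] -
                    brute_force_phi(ell, cam, th[i], d[i], side[i])), 1e-6)
  }
})

test_that("near and far image positions converge as the pupil shrinks", {
  ds <- c(2, 0.5, 0.1, 0.02)
  gaps <- vapply(ds, function(d) {
    pc <- perceived_pupil_center(eye_state(geom, 8, d), cam)
    abs(pc$far_ray_image_pos - pc$near_ray_image_pos)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  # gap shrinks in proportion to the pupil diameter
  expect_lt(gaps[length(gaps)], gaps[1] * (0.02 / 2) * 2)
})

test_that("the two-ray center equals the extremes of a many-ray in-plane fan", {
  # in 2-D, the in-plane pupil perimeter consists of exactly the two edge
  # points; a fan of perimeter samples at fractions of d/2 must be bounded
  # by the +/- d/2 rays
  st <- eye_state(geom, 10, 5)
  fracs <- seq(-1, 1, length.out = 65)
  pos <- vapply(fracs, function(f) {
    if (abs(f) < 1e-12) f <- 1e-12
    psatools:::.solve_edge(geom, cam, 10, 5 * abs(f), sign(f))$image_pos
  }, numeric(1))
  pc <- perceived_pupil_center(st, cam)
  extremes <- range(pos)
  expect_equal(mean(extremes), pc$perceived_center, tolerance = 1e-9)
  expect_equal(min(extremes),
               min(pc$far_ray_image_pos, pc$near_ray_image_pos),
               tolerance = 1e-9)
})

test_that("mirrored viewing angles give mirrored perceived centers", {
  for (th in c(3, 7.5, 12)) {
    p1 <- perceived_pupil_center(eye_state(geom, th, 5), cam)
    p2 <- perceived_pupil_center(eye_state(geom, -th, 5), cam)
    expect_equal(p1$perceived_center, -p2$perceived_center,
                 tolerance = 1e-9)
  }
})
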