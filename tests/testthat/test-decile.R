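test_that("fit_slope matches lm on random points and exact cases", {
  expect_equal(fit_slope(c(1, 3), c(2, 8))$slope, 3)
  # collinear points leave zero residual
  col <- fit_slope(1:7, 2 - 0.5 * (1:7))
  expect_equal(col$slope, -0.5, tolerance = 1e-12)
  expect_lt(max(abs(col$residuals)), 1e-12)
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    ref <- coef(lm(y ~ x))
    f <- fit_slope(x, y)
    expect_equal(f$slope, unname(ref[2]), tolerance = 1e-12)
    expect_equal(f$intercept, unname(ref[1]), tolerance = 1e-12)
  }
  expect_error(fit_slope(c(1, 1), c(2, 3)), "distinct")
})

test_that("decile curves have exactly seven points at the 2nd-8th deciles", {
  set.seed(8)
  tr <- make_trace(runif(2000, 2.5, 5.5), dev_h = rnorm(2000))
  cur <- decile_curve(tr)
  expect_length(cur$decile_x, 7)
  expect_length(cur$mean_dev_y, 7)
  expect_equal(cur$decile_x,
               unname(quantile(tr$pupil, (2:8) / 10)))
  expect_true(all(diff(cur$decile_x) >= 0))
})

test_that("constant deviation gives a flat curve with zero slope", {
  set.seed(12)
  tr <- make_trace(runif(1000, 3, 5), dev_h = rep(1.7, 1000))
  cur <- decile_curve(tr)
  expect_equal(cur$mean_dev_y, rep(1.7, 7))
  expect_equal(cur$slope, 0, tolerance = 1e-12)
})

test_that("band means equal the brute-force recomputation", {
  set.seed(19)
  tr <- make_trace(runif(3000, 2, 6), dev_h = rnorm(3000))
  cur <- decile_curve(tr)
  qs <- quantile(tr$pupil, ((2:9) - 0.5) / 10, names = FALSE)
  for (k in 1:7) {
    sel <- tr$pupil >= qs[k] & tr$pupil < qs[k + 1]
    expect_equal(cur$mean_dev_y[k], mean(tr$dev_h[sel]))
  }
})

test_that("a linear artefact over a uniform pupil is recovered near-exactly", {
  # uniform pupil: half-decile band means coincide with the deciles, so the
  # decile-curve slope equals the raw-sample regression slope
  s <- -0.43; p0 <- 4
  set.seed(1)
  p <- sample(seq(2.5, 5.5, length.out = 20000))
  tr <- make_trace(p, dev_h = s * (p - p0))
  raw <- fit_slope(tr$pupil, tr$dev_h)$slope
  expect_equal(raw, s, tolerance = 1e-12)
  expect_equal(decile_curve(tr)$slope, s, tolerance = 1e-4)
})

test_that("a sinusoidal pupil attenuates the decile slope by the derived factor", {
  # arcsine-distributed pupil: band means are exactly c * (decile - mean)
  # with c = (20/pi) sin(pi/20), so the fitted slope is c * s
  s <- 0.6
  t <- (0:399999) / 1000
  p <- 4 + 1.5 * sin(2 * pi * 0.125 * t)
  tr <- make_trace(p, dev_h = s * (p - 4))
  expect_equal(decile_curve(tr)$slope, sinusoid_band_factor() * s,
               tolerance = 1e-3)
})

test_that("degenerate pupil distributions raise an empty-band error", {
  tr <- make_trace(rep(c(1, 2), each = 50), dev_h = rnorm(100))
  expect_error(decile_curve(tr), "band")
  expect_error(decile_curve(make_trace(runif(10))), "20 valid samples")
})

test_that("pupil must be calibrated to mm", {
  tr <- signal_trace((0:99) / 1000, rnorm(100), rnorm(100),
                     runif(100, 300, 500), pupil_unit = "au")
  expect_error(decile_curve(tr), "mm")
})
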