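test_that("the standard trial is 20 complete cycles of 8 s at 160 s", {
  cfg <- trace_gen_config(cycles = 20, noise_sd = 0, blink_rate = 0)
  expect_equal(cfg$duration, 160)
  g <- gen_trace(cfg)
  expect_equal(nrow(g$trace), 160 * 1000)
  # the pupil signal completes exactly 20 cycles over the trial
  p <- g$trace$pupil
  expect_equal(p[1], 4)
  expect_equal(cfg$f_pupil * cfg$duration, 20)
  # phase at the (virtual) sample after the last equals the starting phase
  expect_equal(4 + 1.5 * sin(2 * pi * 0.125 * 160), p[1], tolerance = 1e-9)
})

test_that("noiseless blink-free traces carry the injected artefact exactly", {
  s <- 0.5
  g <- gen_trace(trace_gen_config(rate = 250, duration = 64, noise_sd = 0,
                                  blink_rate = 0, injected_slope = s,
                                  injected_offset = 1.2, d_ref = 4))
  tr <- g$trace
  expect_true(all(tr$valid))
  expect_equal(tr$dev_h, 1.2 + s * (tr$pupil - 4), tolerance = 1e-12)
  # raw regression recovers the slope exactly; the decile curve recovers it
  # through the derived sinusoid band attenuation
  expect_equal(fit_slope(tr$pupil, tr$dev_h)$slope, s, tolerance = 1e-9)
  expect_equal(decile_curve(tr)$slope, sinusoid_band_factor() * s,
               tolerance = 2e-3)
})

test_that("generation is deterministic given a seed", {
  cfg <- trace_gen_config(rate = 500, duration = 20, seed = 99,
                          blink_rate = 15, noise_sd = 0.2)
  g1 <- gen_trace(cfg); g2 <- gen_trace(cfg)
  expect_identical(g1$trace, g2$trace)
  expect_identical(g1$truth$blink_intervals, g2$truth$blink_intervals)
  g3 <- gen_trace(trace_gen_config(rate = 500, duration = 20, seed = 100,
                                   blink_rate = 15, noise_sd = 0.2))
  expect_false(identical(g1$trace$dev_h, g3$trace$dev_h))
})

test_that("blinks are gaps flanked by fast transients, fully bookkept", {
  cfg <- trace_gen_config(rate = 500, duration = 60, noise_sd = 0,
                          blink_rate = 10, seed = 7)
  g <- gen_trace(cfg)
  tr <- g$trace
  expect_gt(nrow(g$truth$gap_intervals), 0)
  # raw gaps match the ground-truth gap intervals
  for (i in seq_len(nrow(g$truth$gap_intervals))) {
    iv <- g$truth$gap_intervals[i, ]
    inside <- tr$t >= iv[1] & tr$t < iv[2]
    expect_true(all(!tr$valid[inside]))
  }
  # after filtering, lost samples are bounded by blink + pad coverage below
  # and blink + (velocity window + pad) coverage above: the windowed speed
  # is elevated up to one window width beyond each transient ramp
  out <- filter_trace(tr)
  pad_s <- 20 / 1000; win_s <- 20 / 1000
  n_cov <- function(margin) {
    iv <- g$truth$blink_intervals
    sum(pmin(iv[, 2] + margin, 60) - pmax(iv[, 1] - margin, 0)) * 500
  }
  n_blinks <- nrow(g$truth$blink_intervals)
  lost <- sum(!out$valid)
  expect_gte(lost, n_cov(pad_s) - n_blinks)
  expect_lte(lost, n_cov(pad_s + win_s) + n_blinks)
})

test_that("slope recovery is unbiased across noisy blink-laden traces", {
  set.seed(123)
  slopes <- runif(20, -0.7, 0.7)
  errs <- vapply(seq_along(slopes), function(i) {
    g <- gen_trace(trace_gen_config(rate = 250, duration = 80,
                                    injected_slope = slopes[i],
                                    noise_sd = 0.1, blink_rate = 12,
                                    seed = 1000 + i))
    est <- decile_curve(median_center(filter_trace(g$trace)))$slope
    est - slopes[i]
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.02)
})

test_that("invalid generator configurations are rejected", {
  expect_error(trace_gen_config(pupil_mean = 1, pupil_amp = 1.5))
  expect_error(trace_gen_config(rate = -1))
  expect_error(trace_gen_config(f_pupil = 0))
})

test_that("the viewing grid is the eight symmetric directions without zero", {
  g <- gen_viewing_grid()
  expect_equal(g, c(-12, -9, -6, -3, 3, 6, 9, 12))
  expect_length(g, 8)
  expect_equal(sort(-g), g)
  expect_false(0 %in% g)
})
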