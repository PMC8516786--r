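test_that("velocity is zero for constant signals and exact for ramps", {
  tr <- make_trace(rep(4, 500))
  v <- pupil_velocity(tr)
  expect_true(all(v[!is.na(v)] == 0))

  a <- 0.8  # mm/s ramp
  tr2 <- make_trace(4 + a * (0:499) / 1000)
  v2 <- pupil_velocity(tr2)
  expect_equal(v2[!is.na(v2)], rep(a, sum(!is.na(v2))), tolerance = 1e-9)
})

test_that("sinusoid velocity peaks match the analytic derivative with window attenuation", {
  rate <- 1000; f <- 0.125; A <- 1.5
  t <- (0:159999) / rate
  tr <- make_trace(4 + A * sin(2 * pi * f * t), rate = rate)
  v <- pupil_velocity(tr, filter_config(velocity_window = 20))
  # closed-form attenuation of the difference-of-window-means filter
  w <- 20; dt <- 1 / rate; om <- 2 * pi * f
  gain <- (2 / w) * sum(sin(om * (1:w) * dt)) / ((w + 1) * dt * om)
  expect_equal(max(abs(v), na.rm = TRUE), 2 * pi * f * A * gain,
               tolerance = 1e-4)
  # 20 ms windows barely attenuate a 0.125 Hz signal
  expect_gt(gain, 0.9999)
})

test_that("short traces are rejected by the velocity filter", {
  expect_error(pupil_velocity(make_trace(rep(4, 10))), "too short")
})

test_that("a constant trace with zero speed SD loses no samples", {
  tr <- make_trace(rep(4, 1000))
  out <- filter_trace(tr)
  expect_equal(sum(!out$valid), 0)  # strict ">" at SD = 0
  expect_equal(attr(out, "filter_stats")$n_fast, 0)
})

test_that("gap padding widens a 100 ms gap by exactly 20 samples per side", {
  n <- 2000
  valid <- rep(TRUE, n); valid[1001:1100] <- FALSE   # 100 ms at 1000 Hz
  tr <- make_trace(rep(4, n), valid = valid)
  out <- mask_fast_segments(tr, pupil_velocity(tr), filter_config())
  expect_equal(which(!out$valid), 981:1120)
})

test_that("blink flanks are invalidated; result matches the reference pass", {
  g <- gen_trace(trace_gen_config(rate = 500, duration = 30, noise_sd = 0,
                                  blink_rate = 10, seed = 21))
  tr <- g$trace
  out <- filter_trace(tr)
  ref_valid <- reference_filter_mask(ifelse(tr$valid, tr$pupil, NA),
                                     tr$valid, 500)
  expect_equal(out$valid, ref_valid)
  # flanking transients (steep ramps) were removed beyond the raw gaps
  expect_gt(sum(!out$valid), sum(!tr$valid))
})

test_that("data loss accounting is exact and filtering is idempotent", {
  g <- gen_trace(trace_gen_config(rate = 500, duration = 40, noise_sd = 0.1,
                                  blink_rate = 8, seed = 33))
  out <- filter_trace(g$trace)
  expect_equal(data_loss_proportion(out) + mean(out$valid), 1)
  again <- filter_trace(out)
  expect_equal(again$valid, out$valid)
  expect_equal(attr(again, "filter_stats")$threshold,
               attr(out, "filter_stats")$threshold)
})
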