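# run code with a locally-seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic gaze/pupil trace generator
#'
#' Describes the slow-pupil-modulation trial used throughout: a sinusoidal
#' luminance-driven pupil oscillation, a linear pupil-size artefact injected
#' into the horizontal deviation, measurement noise, and blinks (gaps
#' flanked by fast pupil transients).
#'
#' @param rate Sampling rate (Hz); default 1000.
#' @param duration Trial duration (s); default 160. Ignored when `cycles`
#'   is given.
#' @param cycles Optional number of complete pupil cycles; sets
#'   `duration = cycles / f_pupil` (the standard trial is 20 cycles of 8 s).
#' @param f_pupil Pupil modulation frequency (Hz); default 0.125.
#' @param pupil_mean,pupil_amp Mean and amplitude of the pupil-diameter
#'   sinusoid (mm); defaults 4 and 1.5.
#' @param injected_slope Artefact slope (degrees of horizontal deviation per
#'   mm of pupil-diameter change); default 0.
#' @param injected_offset Constant horizontal deviation offset (degrees).
#' @param d_ref Reference (calibration) pupil diameter at which the injected
#'   artefact is zero (mm); default 4.
#' @param noise_sd Gaussian measurement noise SD on both deviation
#'   components (degrees); default 0.1.
#' @param blink_rate Mean blink rate (per minute, Poisson); default 12.
#' @param blink_duration Missing-data duration per blink (ms); default 300.
#' @param transient_slope Pupil speed of the blink-flanking ramps (mm/s);
#'   default 20.
#' @param transient_ms Duration of each flanking ramp (ms); default 60.
#' @param seed Integer seed for reproducibility; `NULL` leaves the RNG
#'   state alone.
#' @return An object of class `trace_gen_config`.
#' @export
trace_gen_config <- function(rate = 1000, duration = 160, cycles = NULL,
                             f_pupil = 0.125, pupil_mean = 4,
                             pupil_amp = 1.5, injected_slope = 0,
                             injected_offset = 0, d_ref = 4,
                             noise_sd = 0.1, blink_rate = 12,
                             blink_duration = 300, transient_slope = 20,
                             transient_ms = 60, seed = NULL) {
  if (!is.null(cycles)) duration <- cycles / f_pupil
  stopifnot(rate > 0, duration > 0, f_pupil > 0,
            pupil_mean - pupil_amp > 0, pupil_amp >= 0,
            noise_sd >= 0, blink_rate >= 0, blink_duration > 0,
            transient_slope >= 0, transient_ms >= 0)
  structure(list(rate = rate, duration = duration, f_pupil = f_pupil,
                 pupil_mean = pupil_mean, pupil_amp = pupil_amp,
                 injected_slope = injected_slope,
                 injected_offset = injected_offset, d_ref = d_ref,
                 noise_sd = noise_sd, blink_rate = blink_rate,
                 blink_duration = blink_duration,
                 transient_slope = transient_slope,
                 transient_ms = transient_ms, seed = seed),
            class = "trace_gen_config")
}

#' Generate a synthetic gaze/pupil trace with ground truth
#'
#' Builds a trial following the slow-pupil-modulation design:
#' `pupil(t) = pupil_mean + pupil_amp * sin(2*pi*f_pupil*t)`, horizontal
#' deviation `injected_offset + injected_slope * (pupil(t) - d_ref)` plus
#' Gaussian noise (the vertical component carries noise only), and
#' Poisson-scheduled blinks: a gap of `blink_duration` ms flanked on each
#' side by a linear pupil ramp of `transient_ms` ms at `transient_slope`
#' mm/s (down into the gap, up out of it).
#'
#' @param cfg A [trace_gen_config()].
#' @return A list with `trace` (a [signal_trace()]) and `truth` (list:
#'   `injected_slope`, `injected_offset`, `d_ref`, `blink_intervals`
#'   (two-column matrix of start/end times in s, ramps included),
#'   `gap_intervals` (missing-data periods only), `seed`).
#' @export
gen_trace <- function(cfg = trace_gen_config()) {
  stopifnot(inherits(cfg, "trace_gen_config"))
  .with_seed(cfg$seed, {
    n <- round(cfg$rate * cfg$duration)
    t <- (seq_len(n) - 1) / cfg$rate
    pupil <- cfg$pupil_mean + cfg$pupil_amp * sin(2 * pi * cfg$f_pupil * t)
    dev_h <- cfg$injected_offset +
      cfg$injected_slope * (pupil - cfg$d_ref)
    dev_v <- rep(0, n)
    if (cfg$noise_sd > 0) {
      dev_h <- dev_h + stats::rnorm(n, 0, cfg$noise_sd)
      dev_v <- dev_v + stats::rnorm(n, 0, cfg$noise_sd)
    }
    valid <- rep(TRUE, n)

    ramp_s <- cfg$transient_ms / 1000
    gap_s <- cfg$blink_duration / 1000
    blink_s <- gap_s + 2 * ramp_s
    n_blinks <- stats::rpois(1, cfg$blink_rate * cfg$duration / 60)
    gaps <- matrix(numeric(0), ncol = 2)
    blinks <- matrix(numeric(0), ncol = 2)
    if (n_blinks > 0) {
      starts <- sort(stats::runif(n_blinks, 0, cfg$duration - blink_s))
      # drop overlapping blinks (keep the earlier one)
      keep <- c(TRUE, diff(starts) > blink_s)
      starts <- starts[keep]
      for (s0 in starts) {
        g0 <- s0 + ramp_s; g1 <- g0 + gap_s
        # descending ramp into the gap, ascending ramp out of it
        in_down <- t >= s0 & t < g0
        in_up <- t >= g1 & t < g1 + ramp_s
        pupil[in_down] <- pupil[in_down] - cfg$transient_slope * (t[in_down] - s0)
        pupil[in_up] <- pupil[in_up] -
          cfg$transient_slope * (g1 + ramp_s - t[in_up])
        valid[t >= g0 & t < g1] <- FALSE
      }
      gaps <- cbind(starts + ramp_s, starts + ramp_s + gap_s)
      blinks <- cbind(starts, starts + blink_s)
    }
    trace <- signal_trace(t, dev_h, dev_v, pupil, valid,
                          rate = cfg$rate, pupil_unit = "mm")
    list(trace = trace,
         truth = list(injected_slope = cfg$injected_slope,
                      injected_offset = cfg$injected_offset,
                      d_ref = cfg$d_ref,
                      blink_intervals = blinks,
                      gap_intervals = gaps,
                      seed = cfg$seed))
  })
}

#' Viewing-direction grid of the frontal-camera experiment
#'
#' The eight viewing directions used when the eye is filmed frontally:
#' -12 to 12 degrees in steps of 3, with the 0-degree direction excluded
#' (the camera occludes the screen center there).
#'
#' @return Numeric vector `c(-12, -9, -6, -3, 3, 6, 9, 12)`.
#' @export
gen_viewing_grid <- function() {
  g <- seq(-12, 12, by = 3)
  g[g != 0]
}
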