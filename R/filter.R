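#' Filtering configuration for pupil traces
#'
#' Parameters of the blink/transient removal step: the window of the
#' difference-of-means velocity filter, the speed threshold in standard
#' deviations, and the padding removed around every gap.
#'
#' @param velocity_window Width of each averaging window of the velocity
#'   filter (ms); default 20.
#' @param sd_multiplier Samples whose pupil speed exceeds the mean by more
#'   than this many standard deviations are invalidated; default 2.
#' @param gap_pad Data additionally removed on each side of every period of
#'   missing data (ms); default 20.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(velocity_window = 20, sd_multiplier = 2,
                          gap_pad = 20) {
  stopifnot(velocity_window > 0, sd_multiplier > 0, gap_pad > 0)
  structure(list(velocity_window = velocity_window,
                 sd_multiplier = sd_multiplier,
                 gap_pad = gap_pad),
            class = "filter_config")
}

#' Pupil-size velocity signal
#'
#' Difference-of-window-means differentiator: the velocity at sample i is
#' the mean pupil size over the `w` samples after i minus the mean over the
#' `w` samples before i, divided by the time between the window centers
#' (`(w + 1)/rate`). Exact for linear ramps; windows touching missing data
#' yield missing velocity.
#'
#' @param trace A [signal_trace()].
#' @param cfg A [filter_config()].
#' @return Numeric velocity per sample (pupil units per second), `NA` where
#'   undefined (trace edges, near gaps).
#' @export
pupil_velocity <- function(trace, cfg = filter_config()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(cfg, "filter_config"))
  rate <- trace_rate(trace)
  w <- max(1L, round(cfg$velocity_window * rate / 1000))
  n <- nrow(trace)
  if (n < 2 * w + 1)
    stop("trace too short for a ", cfg$velocity_window, " ms velocity window")
  p <- trace$pupil
  # trailing mean ending at each sample
  tm <- as.numeric(stats::filter(p, rep(1 / w, w), sides = 1))
  after <- c(tm[(1 + w):n], rep(NA_real_, w))      # mean over (i, i+w]
  before <- c(NA_real_, tm[-n])                    # mean over [i-w, i)
  (after - before) / ((w + 1) / rate)
}

# dilate a logical vector by `pad` samples on each side of every TRUE run
.dilate_runs <- function(x, pad) {
  if (pad <= 0 || !any(x)) return(x)
  n <- length(x)
  idx <- which(x)
  out <- logical(n)
  lo <- pmax(1L, idx - pad)
  hi <- pmin(n, idx + pad)
  # mark [lo, hi] for every run member; vectorized via cumsum of edge marks
  marks <- integer(n + 1L)
  marks[lo] <- marks[lo] + 1L
  marks[hi + 1L] <- marks[hi + 1L] - 1L
  cumsum(marks[-(n + 1L)]) > 0L
}

#' Invalidate fast pupil-size episodes and pad gaps
#'
#' Removes the fast parts of a pupil trace so that only the slow,
#' light-driven changes remain: samples whose pupil speed exceeds the mean
#' speed by more than `sd_multiplier` standard deviations (strictly) are
#' replaced by missing data, and then every contiguous period of missing
#' data is widened by `gap_pad` ms on each side. Mean and SD are computed
#' over the defined speeds of the trace (valid samples only).
#'
#' The pupil *speed* (absolute velocity) is thresholded so that both the
#' downward transient before a blink gap and the upward transient after it
#' are caught.
#'
#' The threshold statistics and the pre-padding ("core") mask are stored in
#' the `filter_stats` attribute of the result, making the step auditable and
#' idempotent: re-filtering a filtered trace (whose stored statistics are
#' reused) invalidates no further samples.
#'
#' @param trace A [signal_trace()].
#' @param velocity Velocity series aligned with `trace`, from
#'   [pupil_velocity()].
#' @param cfg A [filter_config()].
#' @return The filtered `signal_trace`, with attribute `filter_stats`
#'   (list: `mean_speed`, `sd_speed`, `threshold`, `n_fast`, `core_invalid`).
#' @export
mask_fast_segments <- function(trace, velocity, cfg = filter_config()) {
  stopifnot(inherits(trace, "signal_trace"),
            length(velocity) == nrow(trace),
            inherits(cfg, "filter_config"))
  rate <- trace_rate(trace)
  prev <- attr(trace, "filter_stats")
  speed <- abs(velocity)
  if (is.null(prev)) {
    mu <- mean(speed, na.rm = TRUE)
    sdv <- stats::sd(speed, na.rm = TRUE)
    if (is.na(sdv)) sdv <- 0
    thr <- mu + cfg$sd_multiplier * sdv
    core <- !trace$valid
  } else {
    mu <- prev$mean_speed; sdv <- prev$sd_speed; thr <- prev$threshold
    core <- prev$core_invalid
  }
  fast <- !is.na(speed) & speed > thr    # strict: SD = 0 removes nothing
  core <- core | fast
  pad <- round(cfg$gap_pad * rate / 1000)
  invalid <- .dilate_runs(core, pad)
  trace$valid <- trace$valid & !invalid
  trace$dev_h[!trace$valid] <- NA_real_
  trace$dev_v[!trace$valid] <- NA_real_
  trace$pupil[!trace$valid] <- NA_real_
  attr(trace, "filter_stats") <- list(mean_speed = mu, sd_speed = sdv,
                                      threshold = thr, n_fast = sum(fast),
                                      core_invalid = core)
  trace
}

#' Filter a trace (velocity threshold + gap padding)
#'
#' Convenience composition of [pupil_velocity()] and
#' [mask_fast_segments()].
#'
#' @inheritParams mask_fast_segments
#' @return The filtered `signal_trace`.
#' @export
filter_trace <- function(trace, cfg = filter_config()) {
  mask_fast_segments(trace, pupil_velocity(trace, cfg), cfg)
}
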