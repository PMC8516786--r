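#' Gaze/pupil signal trace
#'
#' The tabular container for an eye-tracking trial: a uniformly sampled time
#' series of calibrated gaze deviation (horizontal and vertical, degrees),
#' pupil size, and a per-sample validity flag. Invalid samples carry no
#' deviation or pupil values (they are `NA`).
#'
#' @param t Sample times in seconds, strictly increasing and uniform.
#' @param dev_h,dev_v Horizontal and vertical gaze deviation (degrees).
#' @param pupil Pupil size, in mm or arbitrary units (see `pupil_unit`).
#' @param valid Logical validity flag per sample.
#' @param rate Sampling rate in Hz; inferred from `t` when `NULL`.
#' @param pupil_unit Unit tag for the pupil column, `"mm"` or `"au"`.
#' @return A tibble of class `signal_trace` with columns
#'   `t`, `dev_h`, `dev_v`, `pupil`, `valid` and attributes `rate` and
#'   `pupil_unit`.
#' @export
signal_trace <- function(t, dev_h, dev_v, pupil, valid = NULL,
                         rate = NULL, pupil_unit = c("mm", "au")) {
  pupil_unit <- match.arg(pupil_unit)
  n <- length(t)
  stopifnot(n >= 2, length(dev_h) == n, length(dev_v) == n,
            length(pupil) == n)
  if (is.null(valid)) valid <- !(is.na(pupil) | is.na(dev_h) | is.na(dev_v))
  stopifnot(length(valid) == n, is.logical(valid))
  dt <- diff(t)
  if (any(dt <= 0)) stop("t must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("t must be uniformly sampled")
  if (is.null(rate)) rate <- 1 / mean(dt)
  # invalid samples carry no values
  dev_h[!valid] <- NA_real_
  dev_v[!valid] <- NA_real_
  pupil[!valid] <- NA_real_
  out <- tibble::tibble(t = as.numeric(t), dev_h = as.numeric(dev_h),
                        dev_v = as.numeric(dev_v),
                        pupil = as.numeric(pupil), valid = valid)
  attr(out, "rate") <- rate
  attr(out, "pupil_unit") <- pupil_unit
  class(out) <- c("signal_trace", class(out))
  out
}

# rebuild class/attrs after dplyr-style column surgery
.restore_trace <- function(df, template) {
  attr(df, "rate") <- attr(template, "rate")
  attr(df, "pupil_unit") <- attr(template, "pupil_unit")
  fs <- attr(template, "filter_stats")
  if (!is.null(fs)) attr(df, "filter_stats") <- fs
  if (!inherits(df, "signal_trace"))
    class(df) <- c("signal_trace", class(df))
  df
}

#' Sampling rate of a trace
#' @param trace A [signal_trace()].
#' @return Sampling rate in Hz.
#' @export
trace_rate <- function(trace) attr(trace, "rate")

#' Proportion of lost (invalid) samples
#'
#' The proportion of empty samples in a trial, the standard per-trial data
#' quality measure: invalid-sample count divided by total sample count.
#'
#' @param trace A [signal_trace()].
#' @return A proportion in \[0, 1\].
#' @export
data_loss_proportion <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"), nrow(trace) > 0)
  sum(!trace$valid) / nrow(trace)
}

#' Subtract the median deviation from a trace
#'
#' Centers each deviation component on its per-trial median (computed over
#' valid samples), so trials can be compared by their pupil-size-dependent
#' shape rather than their absolute calibration offset. Pupil size is left
#' untouched.
#'
#' @param trace A [signal_trace()].
#' @return The centered `signal_trace`.
#' @export
median_center <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  ok <- trace$valid
  trace$dev_h <- trace$dev_h - stats::median(trace$dev_h[ok], na.rm = TRUE)
  trace$dev_v <- trace$dev_v - stats::median(trace$dev_v[ok], na.rm = TRUE)
  trace
}

#' Convert the pupil column to millimeters
#'
#' Applies an offline-calibration scale factor (mm per recorded unit) to the
#' pupil column and tags the trace as millimeter-calibrated.
#'
#' @param trace A [signal_trace()].
#' @param mm_per_unit Millimeters per recorded pupil unit.
#' @return The converted `signal_trace` (pupil unit tag `"mm"`).
#' @export
convert_pupil_units <- function(trace, mm_per_unit) {
  stopifnot(inherits(trace, "signal_trace"),
            is.numeric(mm_per_unit), length(mm_per_unit) == 1,
            mm_per_unit > 0)
  trace$pupil <- trace$pupil * mm_per_unit
  attr(trace, "pupil_unit") <- "mm"
  trace
}

#' Pupil foreshortening factor for an oblique viewing angle
#'
#' When the eye is viewed at an angle, the pupil image shrinks by the cosine
#' of the angle between the pupil-plane normal and the camera axis;
#' `foreshortening_factor` returns the factor `1/cos(angle)` by which the
#' true pupil size exceeds its image, and [pupil_underestimation_pct()] the
#' corresponding percentage underestimation of the real pupil size.
#'
#' @param angle Viewing angle in degrees.
#' @return `1/cos(angle)` (dimensionless).
#' @examples
#' foreshortening_factor(60)       # 2
#' pupil_underestimation_pct(12)   # ~2.2 (%)
#' @export
foreshortening_factor <- function(angle) {
  1 / cos(angle * pi / 180)
}

#' @rdname foreshortening_factor
#' @return `pupil_underestimation_pct`: `(1 - cos(angle)) * 100`, percent.
#' @export
pupil_underestimation_pct <- function(angle) {
  (1 - cos(angle * pi / 180)) * 100
}
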