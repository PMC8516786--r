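#' Build the eye-orientation calibration look-up table
#'
#' Simulates the calibration of a virtual pupil-based eye tracker: the eye,
#' with a fixed calibration pupil diameter, is rotated over a dense grid of
#' viewing angles and the perceived pupil center recorded for each angle.
#' The resulting monotone table converts image position back to eye
#' orientation.
#'
#' @param geometry An [eye_geometry()].
#' @param camera A [camera_model()].
#' @param d_cal Calibration pupil diameter (mm); default 4.
#' @param angle_min,angle_max Grid limits (degrees); defaults -20 and 20.
#' @param step Grid step (degrees); default 0.001.
#' @return An object of class `calibration_lut` with fields `angle_grid`,
#'   `center_positions`, `d_cal`, `step`.
#' @export
build_calibration_lut <- function(geometry, camera, d_cal = 4,
                                  angle_min = -20, angle_max = 20,
                                  step = 0.001) {
  stopifnot(inherits(geometry, "eye_geometry"),
            inherits(camera, "camera_model"),
            step > 0, angle_max > angle_min, d_cal > 0)
  angle_grid <- seq(angle_min, angle_max, by = step)
  centers <- .perceived_centers(geometry, camera, angle_grid, d_cal)
  if (anyNA(centers))
    stop("ray tracing failed for ", sum(is.na(centers)),
         " grid angles; angle range exceeds the traceable domain")
  dpos <- diff(centers)
  if (!(all(dpos > 0) || all(dpos < 0)))
    stop("perceived-center positions are not strictly monotone over the ",
         "angle grid; geometry or solver is broken")
  if (all(dpos < 0)) {
    # store ascending in image position so interpolation can bracket directly
    angle_grid <- rev(angle_grid)
    centers <- rev(centers)
  }
  structure(list(angle_grid = angle_grid,
                 center_positions = centers,
                 d_cal = d_cal,
                 step = step),
            class = "calibration_lut")
}

#' Convert a perceived pupil-center position to an apparent eye orientation
#'
#' Inverts the calibration table by linear interpolation between the two
#' bracketing grid entries.
#'
#' @param lut A [build_calibration_lut()] result.
#' @param center_position Image position(s) of the perceived pupil center.
#' @return Apparent viewing angle(s) in degrees.
#' @export
apparent_angle <- function(lut, center_position) {
  stopifnot(inherits(lut, "calibration_lut"))
  rng <- range(lut$center_positions)
  out <- center_position < rng[1] | center_position > rng[2]
  if (any(out, na.rm = TRUE))
    stop("center position outside the calibrated range [",
         signif(rng[1], 6), ", ", signif(rng[2], 6), "]")
  stats::approx(x = lut$center_positions, y = lut$angle_grid,
                xout = center_position, method = "linear",
                ties = "ordered")$y
}

#' @export
print.calibration_lut <- function(x, ...) {
  cat(sprintf(
    "<calibration_lut> %d angles in [%g, %g] deg (step %g), d_cal = %g mm\n",
    length(x$angle_grid), min(x$angle_grid), max(x$angle_grid),
    x$step, x$d_cal))
  invisible(x)
}
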