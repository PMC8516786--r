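#' Simulate the optical pupil-size artefact
#'
#' Runs the full virtual-eye-tracker experiment: a calibration look-up table
#' is built at the calibration pupil diameter, then for each viewing angle
#' the pupil diameter is swept and the artefactual gaze deviation computed
#' as apparent minus real eye orientation. A line fitted to deviation versus
#' pupil diameter summarizes each angle as a slope in degrees per mm.
#'
#' @param geometry An [eye_geometry()].
#' @param camera A [camera_model()]; default [camera_model()].
#' @param viewing_angles Viewing angles to probe (degrees).
#' @param pupil_grid Pupil diameters to sweep (mm).
#' @param d_cal Calibration pupil diameter (mm).
#' @param lut Optionally a precomputed [build_calibration_lut()] (must match
#'   `d_cal`); built on the fly when `NULL`.
#' @return An object of class `psa_sim`: a list with `deviations` (a tibble
#'   with columns `viewing_angle`, `pupil_diameter`, `deviation_deg`),
#'   `slopes` (tibble with `viewing_angle`, `slope_deg_per_mm`,
#'   `intercept_deg`), and the inputs.
#' @examples
#' \donttest{
#' sim <- simulate_psa(eye_geometry(), step = 0.01)
#' sim$slopes
#' }
#' @param step LUT grid step in degrees (passed to
#'   [build_calibration_lut()]).
#' @export
simulate_psa <- function(geometry, camera = camera_model(),
                         viewing_angles = c(-12, -6, 0, 6, 12),
                         pupil_grid = seq(2, 6, by = 0.25),
                         d_cal = 4, lut = NULL, step = 0.001) {
  stopifnot(inherits(geometry, "eye_geometry"))
  if (is.null(lut)) {
    lut <- build_calibration_lut(geometry, camera, d_cal = d_cal, step = step)
  } else {
    stopifnot(inherits(lut, "calibration_lut"))
    if (!isTRUE(all.equal(lut$d_cal, d_cal)))
      stop("supplied LUT was built at d_cal = ", lut$d_cal,
           " mm, not ", d_cal, " mm")
  }
  grid <- expand.grid(pupil_diameter = pupil_grid,
                      viewing_angle = viewing_angles)
  centers <- .perceived_centers(geometry, camera,
                                grid$viewing_angle, grid$pupil_diameter)
  apparent <- apparent_angle(lut, centers)
  dev <- apparent - grid$viewing_angle
  deviations <- tibble::tibble(
    viewing_angle = grid$viewing_angle,
    pupil_diameter = grid$pupil_diameter,
    deviation_deg = dev)
  slopes <- do.call(rbind, lapply(viewing_angles, function(a) {
    sel <- deviations$viewing_angle == a & !is.na(deviations$deviation_deg)
    fit <- fit_slope(deviations$pupil_diameter[sel],
                     deviations$deviation_deg[sel])
    data.frame(viewing_angle = a,
               slope_deg_per_mm = fit$slope,
               intercept_deg = fit$intercept)
  }))
  structure(list(deviations = deviations,
                 slopes = tibble::as_tibble(slopes),
                 viewing_angles = viewing_angles,
                 pupil_grid = pupil_grid,
                 d_cal = d_cal,
                 geometry = geometry,
                 camera = camera),
            class = "psa_sim")
}

#' @export
print.psa_sim <- function(x, ...) {
  cat(sprintf(
    "<psa_sim> %s cornea; %d viewing angles x %d pupil diameters (d_cal = %g mm)\n",
    x$geometry$shape, length(x$viewing_angles), length(x$pupil_grid), x$d_cal))
  cat("Slopes of the optical pupil-size artefact (deg/mm):\n")
  print(as.data.frame(x$slopes), row.names = FALSE)
  invisible(x)
}
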