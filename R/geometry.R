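#' Construct a schematic refracting eye
#'
#' Defines the 2-D (horizontal-plane) reduced eye used throughout the optical
#' simulation: a single refracting corneal surface (circular or elliptical
#' cross-section), an aqueous refractive index behind it, a pupil plane at a
#' fixed depth behind the corneal apex, and a rotation center on the optic
#' axis. Defaults are a Le Grand-style reduced eye.
#'
#' All axial positions are measured along the optic axis with the eye
#' rotation center at the origin and the cornea towards the camera.
#'
#' @param corneal_radius Radius of the circular corneal cross-section (mm).
#'   Ignored when `corneal_semi_axes` is given.
#' @param corneal_semi_axes Optional length-2 numeric `c(axial, transverse)`
#'   semi-axes (mm) for an elliptical corneal cross-section.
#' @param n_outside Refractive index of air in front of the cornea.
#' @param n_inside Refractive index of the medium behind the cornea
#'   (aqueous humour).
#' @param pupil_plane_depth Depth of the pupil (iris) plane behind the
#'   corneal apex (mm). The direction of the simulated artefact is highly
#'   sensitive to this value (see the methods vignette): for this corneal
#'   radius the artefact reverses direction at a depth of about 2.65 mm.
#'   The default, 2.4 mm, is at the shallow end of the human
#'   anterior-chamber range and reproduces the published direction of the
#'   simple-model simulation; anatomically deeper pupil planes (e.g. 3.6
#'   mm, the default of [ellipsoidal_eye()]) give the opposite direction.
#' @param rotation_center_offset Distance from the corneal apex to the eye
#'   rotation center (mm).
#' @param cap_half_angle Angular half-extent of the modeled corneal cap
#'   (degrees of the surface parameter); rays requiring surface points beyond
#'   this cap are reported as occluded.
#' @return An object of class `eye_geometry`.
#' @examples
#' eye <- eye_geometry()
#' eye$apex_x  # corneal apex is 13.5 mm in front of the rotation center
#' @export
eye_geometry <- function(corneal_radius = 7.8,
                         corneal_semi_axes = NULL,
                         n_outside = 1.0,
                         n_inside = 1.336,
                         pupil_plane_depth = 2.4,
                         rotation_center_offset = 13.5,
                         cap_half_angle = 50) {
  if (is.null(corneal_semi_axes)) {
    stopifnot(is.numeric(corneal_radius), length(corneal_radius) == 1,
              corneal_radius > 0)
    semi <- c(corneal_radius, corneal_radius)
    shape <- "sphere"
  } else {
    stopifnot(is.numeric(corneal_semi_axes), length(corneal_semi_axes) == 2,
              all(corneal_semi_axes > 0))
    semi <- as.numeric(corneal_semi_axes)
    shape <- if (semi[1] == semi[2]) "sphere" else "ellipse"
  }
  if (!(n_inside > n_outside && n_outside >= 1))
    stop("refractive indices must satisfy n_inside > n_outside >= 1")
  if (pupil_plane_depth <= 0 || pupil_plane_depth >= rotation_center_offset)
    stop("pupil_plane_depth must lie between the corneal apex and the rotation center")
  if (cap_half_angle <= 0 || cap_half_angle >= 90)
    stop("cap_half_angle must be in (0, 90) degrees")
  structure(
    list(
      shape = shape,
      semi_axes = semi,                      # (axial, transverse) mm
      n_outside = n_outside,
      n_inside = n_inside,
      pupil_plane_depth = pupil_plane_depth,
      rotation_center_offset = rotation_center_offset,
      cap_half_angle = cap_half_angle,
      # derived: apex and surface-curve center on the optic axis
      apex_x = rotation_center_offset,
      center_x = rotation_center_offset - semi[1],
      pupil_x = rotation_center_offset - pupil_plane_depth
    ),
    class = "eye_geometry"
  )
}

#' Elliptical-cornea eye variant
#'
#' A simplified ellipsoidal-cornea eye in the spirit of anatomically detailed
#' schematic eyes: the corneal cross-section is an ellipse rather than a
#' circle, with no apex rotation and no pupil-center decentration, so the
#' optical pupil-size artefact can be isolated. Default semi-axes give an
#' apical radius of curvature of about 7.6 mm
#' (`semi_axis_transverse^2 / semi_axis_axial`).
#'
#' @param semi_axis_axial Ellipse semi-axis along the optic axis (mm).
#' @param semi_axis_transverse Ellipse semi-axis across the optic axis (mm).
#' @param pupil_plane_depth Pupil-plane depth behind the apex (mm); the
#'   default here is the anatomically conventional 3.6 mm, which places this
#'   variant on the other side of the direction reversal discussed in
#'   [eye_geometry()] and so yields an artefact in the opposite direction to
#'   the default spherical model.
#' @param ... Further arguments passed to [eye_geometry()].
#' @return An `eye_geometry` with an elliptical corneal cross-section,
#'   usable in every ray-tracing operation.
#' @export
ellipsoidal_eye <- function(semi_axis_axial = 14.26,
                            semi_axis_transverse = 10.43,
                            pupil_plane_depth = 3.6,
                            ...) {
  if (semi_axis_axial <= 0 || semi_axis_transverse <= 0)
    stop("ellipse semi-axes must be positive")
  args <- list(...)
  if (is.null(args$cap_half_angle)) args$cap_half_angle <- 40
  do.call(eye_geometry,
          c(list(corneal_semi_axes = c(semi_axis_axial, semi_axis_transverse),
                 pupil_plane_depth = pupil_plane_depth),
            args))
}

#' Pinhole camera for the 2-D eye model
#'
#' An ideal perspective camera: all rays pass through a pinhole on the
#' camera axis and are projected onto a 1-D image line. The image coordinate
#' of a ray is `image_plane_distance * tan(alpha)` where `alpha` is the
#' incoming-ray angle relative to the camera axis, which is strictly
#' monotone in `alpha`.
#'
#' @param pinhole_distance Distance from the eye rotation center to the
#'   pinhole (mm); the paper-style default is 530 mm (53 cm).
#' @param image_plane_distance Distance from the pinhole to the image line
#'   (mm); an arbitrary positive scale factor.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pinhole_distance = 530,
                         image_plane_distance = 100) {
  stopifnot(pinhole_distance > 0, image_plane_distance > 0)
  if (pinhole_distance < 100)
    stop("pinhole_distance must be much larger than the eye (>= 100 mm)")
  structure(list(pinhole_distance = pinhole_distance,
                 image_plane_distance = image_plane_distance),
            class = "camera_model")
}

#' Instantaneous eye state
#'
#' Bundles a geometry with a viewing angle and a pupil diameter. The viewing
#' angle is positive when the gaze point is right of the camera (seen from
#' the participant).
#'
#' @param geometry An [eye_geometry()].
#' @param theta Viewing angle in degrees; must lie within the calibration
#'   domain, |theta| <= 20.
#' @param pupil_diameter Pupil diameter in mm.
#' @return An object of class `eye_state`.
#' @export
eye_state <- function(geometry, theta, pupil_diameter) {
  stopifnot(inherits(geometry, "eye_geometry"),
            is.numeric(theta), length(theta) == 1,
            is.numeric(pupil_diameter), length(pupil_diameter) == 1)
  if (abs(theta) > 20)
    stop("|theta| must be <= 20 degrees (calibration domain)")
  iris_bound <- 2 * geometry$semi_axes[2]
  if (pupil_diameter <= 0 || pupil_diameter >= iris_bound)
    stop("pupil_diameter must be positive and smaller than the iris aperture")
  structure(list(geometry = geometry, theta = theta,
                 pupil_diameter = pupil_diameter),
            class = "eye_state")
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat(sprintf(
    "<eye_geometry> %s cornea, semi-axes (%.2f, %.2f) mm\n",
    x$shape, x$semi_axes[1], x$semi_axes[2]))
  cat(sprintf("  n: %.3f -> %.3f; pupil plane %.1f mm behind apex; apex %.1f mm from rotation center\n",
              x$n_inside, x$n_outside, x$pupil_plane_depth,
              x$rotation_center_offset))
  invisible(x)
}
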