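# Ray tracing through the corneal surface to a pinhole camera.
#
# World frame: eye rotation center at the origin, camera pinhole on the +x
# axis at (pinhole_distance, 0). The eye frame is rotated about the origin by
# the viewing angle theta (positive = gaze point right of the camera); the
# corneal surface is parameterized by the arc angle phi measured from the
# optic axis (phi = 0 at the apex).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Evaluate, for surface parameter(s) phi, the signed miss distance of the
# refracted pupil-edge ray with respect to the camera pinhole, plus
# everything needed to reconstruct the ray. All arguments are vectors of
# equal length (or scalars); returns a list of vectors.
.miss_at <- function(phi, geom, camera, theta_rad, d, side) {
  a <- geom$semi_axes[1]; b <- geom$semi_axes[2]
  ct <- cos(theta_rad); st <- sin(theta_rad)

  # surface point and outward normal in the eye frame
  sx_e <- geom$center_x + a * cos(phi)
  sy_e <- b * sin(phi)
  nx_e <- cos(phi) / a
  ny_e <- sin(phi) / b
  nn <- sqrt(nx_e^2 + ny_e^2)
  nx_e <- nx_e / nn; ny_e <- ny_e / nn

  # rotate into the world frame
  sx <- ct * sx_e - st * sy_e
  sy <- st * sx_e + ct * sy_e
  nx <- ct * nx_e - st * ny_e
  ny <- st * nx_e + ct * ny_e

  # pupil-edge point in the world frame
  px_e <- geom$pupil_x
  py_e <- side * d / 2
  px <- ct * px_e - st * py_e
  py <- st * px_e + ct * py_e

  # incident direction (inside the eye, towards the surface)
  ix <- sx - px; iy <- sy - py
  il <- sqrt(ix^2 + iy^2)
  ix <- ix / il; iy <- iy / il

  outward <- ix * nx + iy * ny      # must be > 0 for a physical exit
  ci <- pmax(outward, 0)
  eta <- geom$n_inside / geom$n_outside
  k <- 1 - eta^2 * (1 - ci^2)
  bad <- (outward <= 0) | (k < 0)   # backward exit or total internal reflection
  ctr <- sqrt(pmax(k, 0))
  # transmitted direction: T = eta*I + (eta*ci - ct) * N_opposing, N_opposing = -n
  tx <- eta * ix - (eta * ci - ctr) * nx
  ty <- eta * iy - (eta * ci - ctr) * ny

  cxs <- camera$pinhole_distance - sx
  cys <- -sy
  miss <- tx * cys - ty * cxs       # signed perpendicular miss at the pinhole
  miss[bad | tx <= 0] <- NA_real_
  list(miss = miss, sx = sx, sy = sy, nx = nx, ny = ny,
       ix = ix, iy = iy, tx = tx, ty = ty)
}

# Solve for the corneal exit point of one pupil-edge ray, vectorized over
# states. Returns image positions plus solution diagnostics.
.solve_edge <- function(geom, camera, theta_deg, d, side,
                        n_scan = 81, n_bisect = 64) {
  n <- max(length(theta_deg), length(d), length(side))
  theta_rad <- rep_len(deg2rad(theta_deg), n)
  d <- rep_len(d, n)
  side <- rep_len(side, n)
  phi_max <- deg2rad(geom$cap_half_angle)

  # coarse scan to bracket the root
  grid <- seq(-phi_max, phi_max, length.out = n_scan)
  big_phi <- rep(grid, each = n)
  big <- .miss_at(big_phi, geom, camera,
                  rep.int(theta_rad, n_scan), rep.int(d, n_scan),
                  rep.int(side, n_scan))
  m <- matrix(big$miss, nrow = n, ncol = n_scan)

  lo <- rep(NA_real_, n); hi <- rep(NA_real_, n)
  flo <- rep(NA_real_, n)
  occluded <- rep(FALSE, n)
  # expected exit region: around the camera direction, phi ~ -theta
  target <- -theta_rad
  for (j in seq_len(n_scan - 1)) {
    ok <- !is.na(m[, j]) & !is.na(m[, j + 1]) &
      (sign(m[, j]) != sign(m[, j + 1]))
    if (!any(ok)) next
    cand_mid <- (grid[j] + grid[j + 1]) / 2
    take <- ok & (is.na(lo) | abs(cand_mid - target) <
                    abs((lo + hi) / 2 - target))
    lo[take] <- grid[j]; hi[take] <- grid[j + 1]
    flo[take] <- m[take, j]
  }
  no_solution <- is.na(lo)
  # a root bracket hugging the cap boundary means the true exit point is
  # (at least partly) beyond the modeled cap
  occluded <- !no_solution & (abs(lo) >= phi_max - diff(grid[1:2]) |
                                abs(hi) >= phi_max - diff(grid[1:2]))

  act <- which(!no_solution)
  phi <- rep(NA_real_, n)
  if (length(act)) {
    llo <- lo[act]; lhi <- hi[act]; lflo <- flo[act]
    th <- theta_rad[act]; dd <- d[act]; ss <- side[act]
    for (it in seq_len(n_bisect)) {
      mid <- (llo + lhi) / 2
      fm <- .miss_at(mid, geom, camera, th, dd, ss)$miss
      fm[is.na(fm)] <- 0   # degenerate mid-point: stop moving that bracket
      left <- sign(fm) == sign(lflo) & fm != 0
      llo <- ifelse(left, mid, llo)
      lflo <- ifelse(left, fm, lflo)
      lhi <- ifelse(left, lhi, mid)
    }
    phi[act] <- (llo + lhi) / 2
  }

  sol <- .miss_at(phi, geom, camera, theta_rad, d, side)
  f <- camera$image_plane_distance
  u <- f * sol$ty / sol$tx
  u[no_solution] <- NA_real_
  list(image_pos = u, phi = phi, miss = sol$miss,
       surface_point = cbind(sol$sx, sol$sy),
       normal = cbind(sol$nx, sol$ny),
       incident = cbind(sol$ix, sol$iy),
       transmitted = cbind(sol$tx, sol$ty),
       no_solution = no_solution, occluded = occluded)
}

# Which eye-frame pupil-edge side (+1 / -1) is the "near" edge, i.e. the
# perimeter point whose line of sight from the camera is closest to the
# camera axis. At theta = 0 the two are symmetric and -1 is used.
.near_side <- function(geom, camera, theta_deg, d) {
  th <- deg2rad(theta_deg)
  az <- function(side) {
    px <- cos(th) * geom$pupil_x - sin(th) * side * d / 2
    py <- sin(th) * geom$pupil_x + cos(th) * side * d / 2
    abs(atan2(py, camera$pinhole_distance - px))
  }
  ifelse(az(-1) <= az(1), -1, 1)
}

#' Trace one pupil-perimeter ray to the camera image
#'
#' Solves for the unique ray that leaves the stated pupil-perimeter point
#' (the in-plane pupil edge at plus or minus half the pupil diameter),
#' refracts once at the corneal surface, and passes through the camera
#' pinhole, and returns its image position together with the solved corneal
#' intersection.
#'
#' The "near" edge is the perimeter point whose line of sight from the
#' camera is closest to the camera axis (the edge nearest the nodal ray);
#' "far" is the opposite edge.
#'
#' @param eye An [eye_state()].
#' @param camera A [camera_model()].
#' @param perimeter_point `"near"` or `"far"`.
#' @return A list with `image_pos` (image units), `surface_point`,
#'   `normal`, `incident`, `transmitted` (2-D vectors describing the solved
#'   refraction), `snell_residual`, `miss` (perpendicular pinhole miss
#'   distance of the solved ray, mm), and logical flags `no_solution` and
#'   `occluded`.
#' @export
trace_pupil_ray <- function(eye, camera, perimeter_point = c("near", "far")) {
  stopifnot(inherits(eye, "eye_state"), inherits(camera, "camera_model"))
  perimeter_point <- match.arg(perimeter_point)
  g <- eye$geometry
  near <- .near_side(g, camera, eye$theta, eye$pupil_diameter)
  side <- if (perimeter_point == "near") near else -near
  s <- .solve_edge(g, camera, eye$theta, eye$pupil_diameter, side)
  if (s$no_solution[1])
    return(list(image_pos = NA_real_, no_solution = TRUE, occluded = FALSE))
  res <- snell_residual(s$incident[1, ], s$transmitted[1, ], s$normal[1, ],
                        g$n_inside, g$n_outside)
  list(image_pos = s$image_pos[1],
       phi = s$phi[1],
       surface_point = s$surface_point[1, ],
       normal = s$normal[1, ],
       incident = s$incident[1, ],
       transmitted = s$transmitted[1, ],
       snell_residual = res,
       miss = s$miss[1],
       no_solution = FALSE,
       occluded = s$occluded[1])
}

#' Perceived pupil center in the camera image
#'
#' The apparent (entrance-pupil) center as seen by the camera: the
#' arithmetic mean of the image positions of the refracted far and near
#' pupil-perimeter rays.
#'
#' @inheritParams trace_pupil_ray
#' @return A list with `far_ray_image_pos`, `near_ray_image_pos`,
#'   `perceived_center` (their mean, image units) and flags
#'   `no_solution` / `occluded`.
#' @export
perceived_pupil_center <- function(eye, camera) {
  stopifnot(inherits(eye, "eye_state"), inherits(camera, "camera_model"))
  g <- eye$geometry
  near <- .near_side(g, camera, eye$theta, eye$pupil_diameter)
  sn <- .solve_edge(g, camera, eye$theta, eye$pupil_diameter, near)
  sf <- .solve_edge(g, camera, eye$theta, eye$pupil_diameter, -near)
  bad <- sn$no_solution[1] || sf$no_solution[1]
  list(far_ray_image_pos = sf$image_pos[1],
       near_ray_image_pos = sn$image_pos[1],
       perceived_center = if (bad) NA_real_ else
         (sf$image_pos[1] + sn$image_pos[1]) / 2,
       no_solution = bad,
       occluded = sn$occluded[1] || sf$occluded[1])
}

# Vectorized perceived centers over viewing angles / pupil diameters
# (workhorse for the LUT and the artefact sweep).
.perceived_centers <- function(geom, camera, theta_deg, d) {
  n <- max(length(theta_deg), length(d))
  theta_deg <- rep_len(theta_deg, n); d <- rep_len(d, n)
  s1 <- .solve_edge(geom, camera, theta_deg, d, rep(1, n))
  s2 <- .solve_edge(geom, camera, theta_deg, d, rep(-1, n))
  (s1$image_pos + s2$image_pos) / 2
}
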