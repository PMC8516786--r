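# Independent oracles and small fixtures shared across test files.

# Build a plain trace from vectors, defaulting to a valid, mm-calibrated one.
make_trace <- function(pupil, dev_h = rep(0, length(pupil)),
                       dev_v = rep(0, length(pupil)),
                       valid = rep(TRUE, length(pupil)), rate = 1000) {
  n <- length(pupil)
  signal_trace(t = (seq_len(n) - 1) / rate, dev_h = dev_h, dev_v = dev_v,
               pupil = pupil, valid = valid, rate = rate, pupil_unit = "mm")
}

# Brute-force ray oracle: dense-grid search, written independently of the
# package solver using complex arithmetic. For a pupil-edge point (eye-frame
# side * d/2) it scans the corneal surface parameter phi for the point whose
# refracted ray passes closest to the camera pinhole, then rescans densely
# inside the winning cell. Returns the surface parameter (rad).
brute_force_phi <- function(geom, camera, theta_deg, d, side,
                            n_grid = 20001) {
  th <- theta_deg * pi / 180
  rot <- complex(argument = th)
  a <- geom$semi_axes[1]; b <- geom$semi_axes[2]
  P <- rot * complex(real = geom$pupil_x, imaginary = side * d / 2)
  C <- complex(real = camera$pinhole_distance)
  phi_max <- geom$cap_half_angle * pi / 180

  miss_of <- function(phi) {
    S <- rot * complex(real = geom$center_x + a * cos(phi),
                       imaginary = b * sin(phi))
    nrm <- rot * complex(real = cos(phi) / a, imaginary = sin(phi) / b)
    nrm <- nrm / Mod(nrm)
    din <- (S - P) / Mod(S - P)
    alpha_i <- Arg(din / nrm)                 # signed incidence angle
    sin_t <- geom$n_inside / geom$n_outside * sin(alpha_i)
    m <- rep(Inf, length(phi))
    ok <- abs(sin_t) <= 1 & cos(alpha_i) > 0
    dout <- nrm * complex(argument = asin(pmin(pmax(sin_t, -1), 1)))
    # perpendicular distance of the pinhole from the refracted-ray line
    m[ok] <- abs(Im((C - S[ok]) * Conj(dout[ok])))
    m
  }
  grid <- seq(-phi_max, phi_max, length.out = n_grid)
  i <- which.min(miss_of(grid))
  lo <- grid[max(1, i - 2)]; hi <- grid[min(n_grid, i + 2)]
  fine <- seq(lo, hi, length.out = n_grid)
  fine[which.min(miss_of(fine))]
}

# Straightforward sample-by-sample reference of the filtering step:
# windowed velocity, speed threshold, then pad every invalid run.
reference_filter_mask <- function(pupil, valid, rate, window_ms = 20,
                                  k = 2, pad_ms = 20) {
  n <- length(pupil)
  w <- max(1, round(window_ms * rate / 1000))
  vel <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    before <- pupil[(i - w):(i - 1)]
    after <- pupil[(i + 1):(i + w)]
    vel[i] <- (mean(after) - mean(before)) / ((w + 1) / rate)
  }
  speed <- abs(vel)
  mu <- mean(speed, na.rm = TRUE); sdv <- sd(speed, na.rm = TRUE)
  if (is.na(sdv)) sdv <- 0
  invalid <- !valid | (!is.na(speed) & speed > mu + k * sdv)
  pad <- round(pad_ms * rate / 1000)
  out <- invalid
  for (i in which(invalid)) {
    out[max(1, i - pad):min(n, i + pad)] <- TRUE
  }
  !out
}

# Decile-curve attenuation for a sinusoidally modulated pupil: with
# half-decile bands, band means relate to the decile x-values by this exact
# factor, so a linear artefact of slope s yields a fitted decile slope c*s.
sinusoid_band_factor <- function() (20 / pi) * sin(pi / 20)
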