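#' Refract a ray at a surface (Snell's law, 2-D)
#'
#' Computes the transmitted direction of a ray crossing an interface between
#' media of refractive indices `n1` (incident side) and `n2`, in the plane of
#' incidence. Inputs are 2-D unit vectors; rows are independent rays when
#' matrices are supplied.
#'
#' @param incident Unit direction(s) of the incident ray, numeric length-2
#'   vector or n x 2 matrix.
#' @param normal Unit surface normal(s), same shape as `incident`. Either
#'   orientation of the normal is accepted.
#' @param n1 Refractive index on the incident side.
#' @param n2 Refractive index on the transmitted side.
#' @return An n x 2 matrix of transmitted unit directions (a length-2 vector
#'   when the input was one). Rows are `NA` under total internal reflection,
#'   the distinct no-solution outcome.
#' @examples
#' refract(c(0, -1), c(0, 1), 1, 1.336)      # normal incidence: unchanged
#' @export
refract <- function(incident, normal, n1, n2) {
  one <- is.null(dim(incident))
  I <- rbind(incident); N <- rbind(normal)
  stopifnot(ncol(I) == 2, ncol(N) == 2, nrow(I) == nrow(N),
            n1 > 0, n2 > 0)
  # orient the normal against the incident direction
  flip <- rowSums(I * N) > 0
  N[flip, ] <- -N[flip, ]
  ci <- -rowSums(I * N)              # cos(theta_i) >= 0
  eta <- n1 / n2
  k <- 1 - eta^2 * (1 - ci^2)        # cos^2(theta_t); < 0 => TIR
  ct <- sqrt(pmax(k, 0))
  Tdir <- eta * I + (eta * ci - ct) * N
  Tdir[k < 0, ] <- NA_real_
  if (one) drop(Tdir) else Tdir
}

#' Snell residual of a refraction event
#'
#' Diagnostic helper: `n1*sin(theta_i) - n2*sin(theta_t)` for a solved
#' incident/transmitted pair at a surface normal. Zero (to numerical
#' precision) for a valid refraction.
#'
#' @inheritParams refract
#' @param transmitted Unit direction(s) of the transmitted ray.
#' @return Numeric residual(s).
#' @export
snell_residual <- function(incident, transmitted, normal, n1, n2) {
  I <- rbind(incident); Tr <- rbind(transmitted); N <- rbind(normal)
  cross2 <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]
  # |sin| via cross product with the (unit) normal; signs must agree because
  # incident and transmitted rays lie on the same side of the normal plane
  n1 * cross2(I, N) - n2 * cross2(Tr, N)
}
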