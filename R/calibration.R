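# Second-order polynomial mapping from pupil-minus-CR vectors to screen /
# gaze positions, as fitted during a multi-point calibration.

.poly2_design <- function(xy) {
  xy <- rbind(xy)
  x <- xy[, 1]; y <- xy[, 2]
  cbind(1, x, y, x^2, x * y, y^2)
}

#' Fit a second-order polynomial gaze calibration
#'
#' Maps pupil-minus-CR vectors (px) to known calibration-target positions
#' (degrees or screen units) with a full quadratic in the two vector
#' components, fitted per target axis by least squares. At least six
#' non-degenerate points are required (a ten-point grid is typical).
#'
#' @param features List of [detect_features()] results (or a two-column
#'   matrix of pcr vectors), one per calibration target.
#' @param targets Two-column matrix of target positions, same row count.
#' @return An object of class `poly_calibration`: `coefficients` (6 x 2;
#'   rows 1, x, y, x^2, xy, y^2), `fit_residuals` (n x 2), `rmse` per axis.
#' @export
fit_calibration <- function(features, targets) {
  pcr <- if (is.list(features) && !is.data.frame(features) &&
             !is.matrix(features)) {
    t(vapply(features, function(f) {
      stopifnot(inherits(f, "pupil_cr_features"))
      f$pcr_vector
    }, numeric(2)))
  } else rbind(features)
  targets <- rbind(targets)
  stopifnot(ncol(pcr) == 2, ncol(targets) == 2,
            nrow(pcr) == nrow(targets))
  ok <- stats::complete.cases(pcr) & stats::complete.cases(targets)
  pcr <- pcr[ok, , drop = FALSE]; targets <- targets[ok, , drop = FALSE]
  if (nrow(pcr) < 6)
    stop("need at least 6 non-degenerate calibration points, got ",
         nrow(pcr))
  X <- .poly2_design(pcr)
  qrX <- qr(X)
  if (qrX$rank < 6)
    stop("rank-deficient calibration design (rank ", qrX$rank,
         " of 6): target/vector layout does not span the quadratic terms")
  coef <- qr.coef(qrX, targets)
  fitted <- X %*% coef
  res <- targets - fitted
  structure(list(coefficients = coef,
                 fit_residuals = res,
                 rmse = sqrt(colMeans(res^2)),
                 n_points = nrow(pcr)),
            class = "poly_calibration")
}

#' Apply a polynomial gaze calibration
#'
#' Evaluates the fitted quadratic map on pupil-minus-CR vectors.
#'
#' @param cal A [fit_calibration()] result.
#' @param features A [detect_features()] result, a list of them, or a
#'   two-column matrix of pcr vectors.
#' @return A two-column matrix of gaze positions (target units).
#' @export
apply_calibration <- function(cal, features) {
  stopifnot(inherits(cal, "poly_calibration"))
  pcr <- if (inherits(features, "pupil_cr_features")) {
    rbind(features$pcr_vector)
  } else if (is.list(features) && !is.data.frame(features) &&
             !is.matrix(features)) {
    t(vapply(features, function(f) f$pcr_vector, numeric(2)))
  } else rbind(features)
  .poly2_design(pcr) %*% cal$coefficients
}

#' @export
print.poly_calibration <- function(x, ...) {
  cat(sprintf("<poly_calibration> %d points, RMSE (%.3g, %.3g)\n",
              x$n_points, x$rmse[1], x$rmse[2]))
  invisible(x)
}
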