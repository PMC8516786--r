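#' Ordinary least-squares line fit
#'
#' Unweighted least-squares slope and intercept through a set of points,
#' used both for the seven-point artefact curves (slope in degrees/mm) and
#' for the simulated deviation-versus-pupil sweeps.
#'
#' @param x,y Numeric vectors of equal length (>= 2 distinct x values).
#' @return A list with `slope`, `intercept` and `residuals`.
#' @export
fit_slope <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2 || diff(range(x)) == 0)
    stop("need at least two points with distinct x values")
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  list(slope = slope, intercept = intercept,
       residuals = y - (intercept + slope * x))
}

#' Seven-point pupil-size-artefact curve
#'
#' Summarizes a trace as gaze deviation versus pupil size: the x values are
#' the 2nd to 8th deciles of the valid pupil sizes (steps of one tenth) and
#' each y value is the mean deviation of the samples whose pupil size falls
#' in the half-decile band centered on that decile, i.e. between the
#' quantiles at (k - 0.5)/10 and (k + 0.5)/10. A line fitted through the
#' seven points gives the artefact slope in degrees per mm.
#'
#' @param trace A [signal_trace()] with pupil size in mm.
#' @param component `"horizontal"` or `"vertical"` deviation component.
#' @return An object of class `psa_curve`: list with `decile_x` (mm, 7
#'   values), `mean_dev_y` (degrees, 7 values), `slope` (degrees/mm),
#'   `intercept` (degrees), `component`, `n_valid`.
#' @export
decile_curve <- function(trace, component = c("horizontal", "vertical")) {
  component <- match.arg(component)
  stopifnot(inherits(trace, "signal_trace"))
  if (!identical(attr(trace, "pupil_unit"), "mm"))
    stop("pupil size must be in mm; see convert_pupil_units()")
  dev <- if (component == "horizontal") trace$dev_h else trace$dev_v
  ok <- trace$valid & !is.na(trace$pupil) & !is.na(dev)
  p <- trace$pupil[ok]; y <- dev[ok]
  if (length(p) < 20)
    stop("need at least 20 valid samples for a decile curve")
  ks <- 2:8
  qx <- stats::quantile(p, probs = ks / 10, names = FALSE, type = 7)
  edges <- stats::quantile(p, probs = (c(ks, max(ks) + 1) - 0.5) / 10,
                           names = FALSE, type = 7)
  ym <- vapply(seq_along(ks), function(i) {
    inband <- p >= edges[i] & p < edges[i + 1]
    if (!any(inband))
      stop("no samples in pupil-size band ", ks[i],
           " [", signif(edges[i], 6), ", ", signif(edges[i + 1], 6), ")")
    mean(y[inband])
  }, numeric(1))
  fit <- fit_slope(qx, ym)
  structure(list(decile_x = qx, mean_dev_y = ym,
                 slope = fit$slope, intercept = fit$intercept,
                 component = component, n_valid = length(p)),
            class = "psa_curve")
}

#' @export
print.psa_curve <- function(x, ...) {
  cat(sprintf("<psa_curve> %s component, %d valid samples\n",
              x$component, x$n_valid))
  print(data.frame(pupil_decile_mm = x$decile_x,
                   mean_deviation_deg = x$mean_dev_y), row.names = FALSE)
  cat(sprintf("slope: %.4f deg/mm, intercept: %.4f deg\n",
              x$slope, x$intercept))
  invisible(x)
}
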