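# Pupil / corneal-reflection detection on monochrome eye frames:
# threshold -> connected components -> size/shape criteria -> center of mass.

#' Size and shape criteria for candidate blobs
#'
#' Regions unlikely to belong to a pupil or a CR are excluded by area
#' bounds, the axis ratio of the moment-equivalent ellipse, and the fill
#' fraction (blob area over equivalent-ellipse area).
#'
#' @param min_area,max_area Area bounds (px^2).
#' @param max_axis_ratio Maximum major/minor axis ratio of the fitted
#'   ellipse (>= 1); default 2.
#' @param min_fill_fraction Minimum area / ellipse-area fraction in (0, 1\];
#'   default 0.6.
#' @return An object of class `blob_criteria`.
#' @export
blob_criteria <- function(min_area = 50, max_area = 20000,
                          max_axis_ratio = 2, min_fill_fraction = 0.6) {
  stopifnot(min_area < max_area, min_area > 0,
            max_axis_ratio >= 1,
            min_fill_fraction > 0, min_fill_fraction <= 1)
  structure(list(min_area = min_area, max_area = max_area,
                 max_axis_ratio = max_axis_ratio,
                 min_fill_fraction = min_fill_fraction),
            class = "blob_criteria")
}

# label a logical mask into 8-connected components; returns a list of
# two-column (x, y) pixel-coordinate matrices
.connected_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  h <- nrow(mask)
  # ids of the 8 neighbours of each foreground pixel, as graph edges
  y <- (idx - 1L) %% h + 1L
  x <- (idx - 1L) %/% h + 1L
  lookup <- integer(length(mask)); lookup[idx] <- seq_along(idx)
  edges <- NULL
  for (dd in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nx <- x + dd[1]; ny <- y + dd[2]
    ok <- nx >= 1L & nx <= ncol(mask) & ny >= 1L & ny <= h
    nidx <- (nx[ok] - 1L) * h + ny[ok]
    nb <- lookup[nidx]
    hit <- nb > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], nb[hit]))
  }
  if (is.null(edges)) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  }
  split.data.frame(cbind(x = x, y = y), memb)
}

# second-moment (moment-equivalent ellipse) statistics of a blob
.blob_shape <- function(px) {
  n <- nrow(px)
  cx <- mean(px[, 1]); cy <- mean(px[, 2])
  # add the 1/12 variance of a unit pixel so single pixels behave as squares
  sxx <- mean((px[, 1] - cx)^2) + 1 / 12
  syy <- mean((px[, 2] - cy)^2) + 1 / 12
  sxy <- mean((px[, 1] - cx) * (px[, 2] - cy))
  tr <- sxx + syy
  det <- sxx * syy - sxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)   # semi-axes of equivalent ellipse
  list(center = c(cx, cy), area = n,
       axis_ratio = a / b, fill_fraction = n / (pi * a * b))
}

#' Extract candidate pupil and CR blobs by thresholding
#'
#' Thresholds the frame into a very-dark mask (pupil candidates, intensity
#' <= `dark_threshold`) and a very-bright mask (CR candidates, intensity >=
#' `bright_threshold`), and labels each mask into 8-connected components.
#'
#' @param image An `eye_image` (see [as_eye_image()]).
#' @param dark_threshold,bright_threshold Intensity thresholds (0-255).
#' @return A list with `dark` and `bright`: each a list of blobs, where a
#'   blob is a two-column matrix of (x, y) pixel coordinates.
#' @export
extract_blobs <- function(image, dark_threshold, bright_threshold) {
  stopifnot(inherits(image, "eye_image"),
            dark_threshold >= 0, dark_threshold <= 255,
            bright_threshold >= 0, bright_threshold <= 255)
  m <- unclass(image)
  list(dark = .connected_components(m <= dark_threshold),
       bright = .connected_components(m >= bright_threshold))
}

#' Filter blobs by size and shape criteria
#'
#' @param blobs List of blobs from [extract_blobs()].
#' @param criteria A [blob_criteria()].
#' @return The blobs passing all criteria.
#' @export
filter_blobs <- function(blobs, criteria = blob_criteria()) {
  stopifnot(inherits(criteria, "blob_criteria"))
  keep <- vapply(blobs, function(b) {
    s <- .blob_shape(b)
    s$area >= criteria$min_area && s$area <= criteria$max_area &&
      s$axis_ratio <= criteria$max_axis_ratio &&
      s$fill_fraction >= criteria$min_fill_fraction
  }, logical(1))
  blobs[keep]
}

#' Binary center of mass of a blob
#'
#' The unweighted centroid of the blob's member pixel coordinates.
#'
#' @param blob Two-column (x, y) pixel-coordinate matrix.
#' @return Numeric length-2 `(x, y)` center in px.
#' @export
blob_center <- function(blob) {
  stopifnot(is.matrix(blob) || is.data.frame(blob), ncol(blob) == 2)
  c(x = mean(blob[, 1]), y = mean(blob[, 2]))
}

#' Mean position of the k lowest corneal reflections
#'
#' Selects the `k` CR candidates lowest in the image (largest y; ties
#' broken by horizontal order, leftmost first) and returns their mean
#' position, the CR reference used for gaze estimation.
#'
#' @param cr_centers Two-column (x, y) matrix of CR candidate centers.
#' @param k Number of reflections to average; default 3.
#' @return Numeric `(x, y)` mean position.
#' @export
select_lower_crs <- function(cr_centers, k = 3) {
  cr_centers <- rbind(cr_centers)
  if (nrow(cr_centers) < k)
    stop("fewer than ", k, " CR candidates; frame invalid")
  ord <- order(-cr_centers[, 2], cr_centers[, 1])
  sel <- cr_centers[ord[seq_len(k)], , drop = FALSE]
  c(x = mean(sel[, 1]), y = mean(sel[, 2]))
}

#' Detect pupil and CR features in an eye frame
#'
#' The full per-frame feature extraction of a pupil-minus-CR tracker:
#' thresholding, 8-connected labeling, size/shape filtering with separate
#' pupil and CR criteria, binary centers of mass, lower-CR averaging, and
#' the pupil-minus-CR vector.
#'
#' @param image An `eye_image`.
#' @param dark_threshold,bright_threshold Intensity thresholds (0-255).
#' @param pupil_criteria,cr_criteria [blob_criteria()] for the pupil and
#'   the CRs; defaults: pupil area 50-20000 px^2, CR area 4-400 px^2, both
#'   with axis ratio <= 2 and fill fraction >= 0.6.
#' @param n_crs Number of lower CRs averaged; default 3.
#' @return An object of class `pupil_cr_features`: list with
#'   `pupil_center`, `cr_centers` (matrix of all accepted CRs), `cr_mean`
#'   (mean of the `n_crs` lowest), `pcr_vector`
#'   (`pupil_center - cr_mean`), and `valid` (FALSE with `reason` when no
#'   unique pupil or too few CRs were found).
#' @export
detect_features <- function(image, dark_threshold, bright_threshold,
                            pupil_criteria = blob_criteria(50, 20000),
                            cr_criteria = blob_criteria(4, 400),
                            n_crs = 3) {
  blobs <- extract_blobs(image, dark_threshold, bright_threshold)
  pupils <- filter_blobs(blobs$dark, pupil_criteria)
  crs <- filter_blobs(blobs$bright, cr_criteria)
  fail <- function(reason)
    structure(list(pupil_center = c(NA_real_, NA_real_),
                   cr_centers = NULL, cr_mean = c(NA_real_, NA_real_),
                   pcr_vector = c(NA_real_, NA_real_),
                   valid = FALSE, reason = reason),
              class = "pupil_cr_features")
  if (length(pupils) == 0) return(fail("no pupil candidate"))
  if (length(pupils) > 1) {
    # the pupil is the largest accepted dark blob
    pupils <- pupils[order(-vapply(pupils, nrow, integer(1)))[1]]
  }
  if (length(crs) < n_crs) return(fail("too few CR candidates"))
  pupil_center <- blob_center(pupils[[1]])
  cr_centers <- t(vapply(crs, blob_center, numeric(2)))
  cr_mean <- select_lower_crs(cr_centers, n_crs)
  structure(list(pupil_center = pupil_center,
                 cr_centers = cr_centers,
                 cr_mean = cr_mean,
                 pcr_vector = pupil_center - cr_mean,
                 valid = TRUE, reason = NULL),
            class = "pupil_cr_features")
}
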