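#' Configuration for the synthetic eye-image renderer
#'
#' Describes a monochrome eye frame as a pupil-minus-CR tracker sees it: a
#' uniform iris background, a dark pupil disk, and a set of bright
#' Gaussian-profile corneal-reflection (CR) spots. The default CR layout is
#' six spots in two rows of three below the pupil center, emulating a
#' six-LED illuminator.
#'
#' Image coordinates: origin at the top-left, x rightward, y downward,
#' pixel centers at integer coordinates ("lower" in the image = larger y).
#'
#' @param width,height Frame size in pixels.
#' @param iris_gray,pupil_gray,cr_gray Iris background, pupil, and CR peak
#'   intensities (8-bit scale, 0-255).
#' @param pupil_center Length-2 numeric, sub-pixel pupil center (x, y).
#' @param pupil_radius Pupil radius (px).
#' @param cr_positions Two-column matrix of CR centers (x, y), px.
#' @param cr_sigma Gaussian sigma of each CR spot (px).
#' @param noise_sd Gaussian pixel-noise SD (intensity units); default 0.
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `image_gen_config`.
#' @export
image_gen_config <- function(width = 320, height = 240,
                             iris_gray = 120, pupil_gray = 20,
                             cr_gray = 250,
                             pupil_center = c(160, 110),
                             pupil_radius = 40,
                             cr_positions = NULL,
                             cr_sigma = 1.8,
                             noise_sd = 0, seed = NULL) {
  if (is.null(cr_positions)) {
    cx <- pupil_center[1]; cy <- pupil_center[2]
    cr_positions <- cbind(
      x = rep(cx + c(-30, 0, 30), 2),
      y = rep(cy + c(52, 64), each = 3))
  }
  cr_positions <- rbind(cr_positions)
  stopifnot(width > 0, height > 0,
            pupil_gray < iris_gray, cr_gray > iris_gray,
            pupil_radius > 0, cr_sigma > 0, noise_sd >= 0,
            ncol(cr_positions) == 2)
  r <- pupil_radius
  if (pupil_center[1] - r < 1 || pupil_center[1] + r > width ||
      pupil_center[2] - r < 1 || pupil_center[2] + r > height)
    stop("pupil disk extends outside the frame")
  if (any(cr_positions[, 1] < 1 | cr_positions[, 1] > width |
          cr_positions[, 2] < 1 | cr_positions[, 2] > height))
    stop("CR position outside the frame")
  structure(list(width = width, height = height, iris_gray = iris_gray,
                 pupil_gray = pupil_gray, cr_gray = cr_gray,
                 pupil_center = as.numeric(pupil_center),
                 pupil_radius = pupil_radius,
                 cr_positions = cr_positions, cr_sigma = cr_sigma,
                 noise_sd = noise_sd, seed = seed),
            class = "image_gen_config")
}

#' Render a synthetic eye image with ground truth
#'
#' Draws the frame described by an [image_gen_config()]: the pupil disk is
#' anti-aliased by 4x4 supersampling (each pixel's darkness is the fraction
#' of 16 subsamples inside the disk), CR spots have a Gaussian intensity
#' profile added on top, and optional Gaussian pixel noise is applied before
#' clipping to the 8-bit range and rounding to whole intensity levels.
#'
#' @param cfg An [image_gen_config()].
#' @return A list with `image` (an `eye_image`: integer matrix, rows = y,
#'   columns = x, values 0-255) and `truth` (exact sub-pixel
#'   `pupil_center`, `pupil_radius`, `cr_positions`, `seed`).
#' @export
render_eye_image <- function(cfg = image_gen_config()) {
  stopifnot(inherits(cfg, "image_gen_config"))
  ss <- 4L
  # subsample coordinates: pixel (ix, iy) covers ix +/- 0.5; subsample
  # centers at ix - 0.5 + (k - 0.5)/ss
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  xs <- rep(seq_len(cfg$width), each = 1)
  cov <- matrix(0, nrow = cfg$height, ncol = cfg$width)
  for (oy in off) for (ox in off) {
    dx2 <- (xs + ox - cfg$pupil_center[1])^2
    dy2 <- (seq_len(cfg$height) + oy - cfg$pupil_center[2])^2
    cov <- cov + (outer(dy2, dx2, "+") <= cfg$pupil_radius^2)
  }
  cov <- cov / ss^2
  img <- cfg$iris_gray + (cfg$pupil_gray - cfg$iris_gray) * cov
  for (i in seq_len(nrow(cfg$cr_positions))) {
    dx2 <- (seq_len(cfg$width) - cfg$cr_positions[i, 1])^2
    dy2 <- (seq_len(cfg$height) - cfg$cr_positions[i, 2])^2
    g <- exp(-outer(dy2, dx2, "+") / (2 * cfg$cr_sigma^2))
    img <- img + (cfg$cr_gray - cfg$iris_gray) * g
  }
  img <- .with_seed(cfg$seed, {
    if (cfg$noise_sd > 0)
      img + stats::rnorm(length(img), 0, cfg$noise_sd)
    else img
  })
  img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))),
                nrow = cfg$height, ncol = cfg$width)
  class(img) <- c("eye_image", class(img))
  list(image = img,
       truth = list(pupil_center = cfg$pupil_center,
                    pupil_radius = cfg$pupil_radius,
                    cr_positions = cfg$cr_positions,
                    seed = cfg$seed))
}

#' Coerce a grayscale array to an 8-bit eye image
#'
#' Accepts an integer matrix of 8-bit intensities, a 10-bit matrix (values
#' above 255 are right-shifted to 8 bits before processing), or a numeric
#' array in \[0, 1\] as returned by [png::readPNG()] (grayscale, or RGB(A)
#' with equal channels).
#'
#' @param x Matrix or array of pixel intensities.
#' @param bit_depth Input bit depth, 8 or 10; default 8. Ignored for
#'   \[0, 1\] numeric input.
#' @return An `eye_image` (integer matrix, 0-255; rows = y, columns = x).
#' @export
as_eye_image <- function(x, bit_depth = 8) {
  if (length(dim(x)) == 3) x <- x[, , 1]            # RGB(A) -> first channel
  stopifnot(is.matrix(x))
  if (is.double(x) && max(x, na.rm = TRUE) <= 1) {
    img <- round(x * 255)
  } else if (bit_depth == 10) {
    img <- x %/% 4L                                  # right-shift to 8 bit
  } else if (bit_depth == 8) {
    img <- x
  } else stop("bit_depth must be 8 or 10")
  if (min(img) < 0 || max(img) > 255)
    stop("intensities outside the 8-bit range after conversion")
  img <- matrix(as.integer(img), nrow = nrow(x), ncol = ncol(x))
  class(img) <- c("eye_image", class(img))
  img
}

#' Write an eye image as an 8-bit grayscale PNG
#'
#' @param image An `eye_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eye_image_png <- function(image, path) {
  stopifnot(inherits(image, "eye_image"))
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' Read a grayscale PNG as an eye image
#'
#' @param path PNG file path.
#' @return An `eye_image`.
#' @export
read_eye_image_png <- function(path) {
  as_eye_image(png::readPNG(path))
}
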