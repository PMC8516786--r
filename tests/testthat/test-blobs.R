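test_that("thresholding yields the expected blobs on basic frames", {
  flat <- as_eye_image(matrix(128L, 40, 60))
  b <- extract_blobs(flat, 60, 200)
  expect_length(b$dark, 0)
  expect_length(b$bright, 0)
  # extreme thresholds select everything / nothing
  ball <- extract_blobs(flat, 255, 0)
  expect_equal(nrow(ball$dark[[1]]), 40 * 60)
  expect_equal(nrow(ball$bright[[1]]), 40 * 60)

  r <- render_eye_image(image_gen_config())
  bb <- extract_blobs(r$image, 60, 200)
  expect_length(bb$dark, 1)
  expect_length(bb$bright, 6)
})

test_that("connected components use 8-connectivity", {
  m <- matrix(255L, 10, 10)
  m[2, 2] <- 0L; m[3, 3] <- 0L   # touch only diagonally
  b <- extract_blobs(as_eye_image(m), 10, 255)
  expect_length(b$dark, 1)
  expect_equal(nrow(b$dark[[1]]), 2)
})

test_that("size and shape criteria exclude implausible regions", {
  crit <- blob_criteria(min_area = 30, max_area = 4000,
                        max_axis_ratio = 2, min_fill_fraction = 0.6)
  # a clean disk passes
  r <- render_eye_image(image_gen_config(pupil_radius = 20))
  disk <- extract_blobs(r$image, 60, 255)$dark
  expect_length(filter_blobs(disk, crit), 1)
  # oversized blob removed
  expect_length(filter_blobs(disk, blob_criteria(1, 100)), 0)
  # a thin eyelash-like streak fails the axis-ratio bound
  m <- matrix(200L, 60, 60)
  m[30, 5:55] <- 0L
  streak <- extract_blobs(as_eye_image(m), 10, 255)$dark
  expect_length(streak, 1)
  expect_length(filter_blobs(streak, crit), 0)
})

test_that("blob centers are binary centers of mass", {
  expect_equal(blob_center(cbind(10, 20)), c(x = 10, y = 20))
  # translation equivariance
  set.seed(3)
  blob <- cbind(sample(5:15, 30, TRUE), sample(5:15, 30, TRUE))
  c0 <- blob_center(blob)
  c1 <- blob_center(blob + matrix(rep(c(7, -3), each = 30), ncol = 2))
  expect_equal(c1, c0 + c(x = 7, y = -3))
  # rasterized disk centroid is within 0.2 px of the analytic center
  r <- render_eye_image(image_gen_config(pupil_center = c(161.3, 109.6)))
  d <- extract_blobs(r$image, 60, 255)$dark[[1]]
  expect_lt(sqrt(sum((blob_center(d) - c(161.3, 109.6))^2)), 0.2)
})

test_that("the lowest-k CR rule averages the lower row deterministically", {
  three <- cbind(c(10, 20, 30), c(5, 6, 7))
  expect_equal(select_lower_crs(three, 3), c(x = 20, y = 6))
  two_rows <- cbind(rep(c(10, 20, 30), 2), rep(c(40, 80), each = 3))
  expect_equal(select_lower_crs(two_rows, 3), c(x = 20, y = 80))
  # vertical ties broken by horizontal order, leftmost first
  tied <- cbind(c(30, 10, 20), c(50, 50, 50))
  expect_equal(select_lower_crs(tied, 2), c(x = 15, y = 50))
  expect_error(select_lower_crs(three, 4), "fewer than 4")
})

test_that("detect_features flags frames without a usable pupil or CRs", {
  flat <- as_eye_image(matrix(128L, 40, 60))
  f <- detect_features(flat, 60, 200)
  expect_false(f$valid)
  expect_match(f$reason, "pupil")
  # pupil but too few CRs
  r <- render_eye_image(image_gen_config(cr_positions = cbind(100, 200)))
  f2 <- detect_features(r$image, 60, 200)
  expect_false(f2$valid)
  expect_match(f2$reason, "CR")
})
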