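# Segmentation and binary shape features.

square_mask <- function(canvas = 32, side = 10, at = c(8, 8)) {
  m <- matrix(FALSE, canvas, canvas)
  m[at[1]:(at[1] + side - 1), at[2]:(at[2] + side - 1)] <- TRUE
  m
}

disk_mask <- function(canvas, radius, ctr = (canvas + 1) / 2) {
  r <- matrix(seq_len(canvas), canvas, canvas) - ctr
  c <- t(r)
  r^2 + c^2 <= radius^2
}

test_that("binarize_object separates bright halves and keeps the largest blob", {
  img <- matrix(0.1, 16, 16)
  img[, 9:16] <- 0.9
  m <- binarize_object(img)
  expect_true(all(m[, 9:16]) && !any(m[, 1:8]))

  expect_error(binarize_object(matrix(0.5, 16, 16)),
               class = "mrigrade_validation_error")

  img2 <- matrix(0.05, 32, 32)
  img2[2:11, 2:6] <- 0.9    # 50-pixel blob
  img2[20:24, 20:21] <- 0.9 # 10-pixel blob
  m2 <- binarize_object(img2)
  expect_equal(sum(m2), 50)
  expect_true(all(m2[2:11, 2:6]))
})

test_that("region_metrics reproduces closed-form values for squares and holes", {
  rm <- region_metrics(square_mask())
  expect_equal(unname(rm["area"]), 100)
  expect_equal(unname(rm["extent"]), 1)
  expect_equal(unname(rm["solidity"]), 1)
  expect_equal(unname(rm["euler"]), 1)
  expect_equal(unname(rm["bbox_height"]), 10)
  expect_equal(unname(rm["bbox_width"]), 10)
  expect_equal(unname(rm["equiv_diameter"]), sqrt(400 / pi), tolerance = 1e-12)
  expect_equal(unname(rm["filled_area"]), 100)
  expect_equal(unname(rm["centroid_row"]), 12.5)

  holed <- square_mask()
  holed[12:13, 12:13] <- FALSE  # 2x2 interior hole
  rh <- region_metrics(holed)
  expect_equal(unname(rh["euler"]), 0)
  expect_equal(unname(rh["area"]), 96)
  expect_equal(unname(rh["filled_area"]), 100)

  expect_error(region_metrics(matrix(FALSE, 8, 8)),
               class = "mrigrade_validation_error")
})

test_that("region metrics are translation invariant except centroid", {
  m1 <- square_mask(40, 12, c(5, 7))
  m2 <- square_mask(40, 12, c(21, 18))
  r1 <- region_metrics(m1); r2 <- region_metrics(m2)
  moving <- c("centroid_row", "centroid_col")
  expect_equal(r1[setdiff(names(r1), moving)], r2[setdiff(names(r2), moving)],
               tolerance = 1e-9)
})

test_that("bibs_signature matches ray geometry for disks and 2:1 ellipses", {
  d <- disk_mask(64, 20)
  sig <- bibs_signature(d, 8L)
  expect_equal(max(sig), 1)
  expect_true(all(abs(sig - 1) <= 0.1))  # circular symmetry within grid error

  r <- matrix(seq_len(64), 64, 64) - 32.5
  c <- t(r)
  ell <- (c / 24)^2 + (r / 12)^2 <= 1    # 2:1 wide ellipse
  s4 <- bibs_signature(ell, 4L)
  expect_equal(s4, c(1, 0.5, 1, 0.5), tolerance = 0.1)

  # scale invariance within grid error
  s_small <- bibs_signature(disk_mask(32, 10), 8L)
  s_large <- bibs_signature(disk_mask(96, 30), 8L)
  expect_equal(s_small, s_large, tolerance = 0.1)
})

test_that("fractal dimension distinguishes solid regions, lines and points", {
  solid <- matrix(TRUE, 64, 64)
  expect_true(fractal_dimension(solid) >= 1.8 && fractal_dimension(solid) <= 2)

  line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
  dl <- fractal_dimension(line)
  expect_true(dl >= 0.9 && dl <= 1.1)

  pt <- matrix(FALSE, 64, 64); pt[10, 50] <- TRUE
  expect_equal(fractal_dimension(pt), 0)

  for (seed in 1:3) {
    m <- random_image(32, seed) > 0.6
    if (any(m)) {
      fd <- fractal_dimension(m)
      expect_true(fd >= 0 && fd <= 2)
    }
  }
})

test_that("shape signature aspect ratio follows the boundary bounding box", {
  expect_equal(shape_signature_aspect(square_mask()), 1)
  rect <- matrix(FALSE, 32, 32)
  rect[11:20, 6:25] <- TRUE   # 10 tall x 20 wide
  expect_equal(shape_signature_aspect(rect), 2)
  expect_gt(shape_signature_aspect(disk_mask(32, 9)), 0)
})
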