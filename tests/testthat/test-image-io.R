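# Image reading, writing, resizing, dataset loading and stratified splits.

test_that("PNG round trip preserves pixels to 8-bit precision and RGB collapses by luminance", {
  img <- random_image(16, seed = 41)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f)
  back <- read_image(f)
  expect_true(max(abs(back - img)) <= 1 / 255)

  # RGB white must map to exactly 1 (weights sum to 1), black to 0
  rgb <- array(0, c(8, 8, 3))
  rgb[1:4, , ] <- 1
  f2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgb, f2)
  g <- read_image(f2)
  expect_equal(g[1, 1], 1)
  expect_equal(g[8, 8], 0)
  expect_true(is.matrix(g))

  expect_error(read_image(file.path(tempdir(), "no_such_file.png")),
               class = "mrigrade_io_error")
})

test_that("bilinear rescale handles identity, constants, and a 2x2 checkerboard", {
  img <- random_image(32, seed = 42)
  expect_identical(rescale(img, c(32, 32)), img)

  const <- matrix(0.5, 16, 16)
  expect_equal(rescale(const, c(24, 24)), matrix(0.5, 24, 24), tolerance = 1e-12)

  # 2x2 checkerboard upsampled to 4x4: direct bilinear formula.
  # Output centres map to input coords {0, 0.5, 1} (clamped); the corner
  # output pixels coincide with the input pixels.
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  up <- rescale(cb, c(8, 8))  # min target is 8
  expect_true(all(up >= 0 & up <= 1))
  expect_equal(up[1, 1], cb[1, 1])
  expect_equal(up[8, 8], cb[2, 2])
  expect_equal(up[1, 8], cb[1, 2])
  expect_error(rescale(img, c(4, 4)), class = "mrigrade_validation_error")
})

make_dataset_dir <- function(n_per_class = 3, size = 16, seed = 1) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  set.seed(seed)
  for (cl in c("NonDemented", "VeryMild", "Mild", "Moderate")) {
    dir.create(file.path(root, cl))
    for (i in seq_len(n_per_class)) {
      write_image(matrix(runif(size^2), size, size),
                  file.path(root, cl, sprintf("img_%02d.png", i)))
    }
  }
  root
}

test_that("load_labeled_dataset assigns labels from directories in fixed order, deterministically", {
  root <- make_dataset_dir(3)
  ds <- load_labeled_dataset(root)
  expect_s3_class(ds, "labeled_dataset")
  expect_length(ds, 12)
  expect_equal(as.vector(table(ds$labels)), rep(3L, 4))
  ds2 <- load_labeled_dataset(root)
  expect_identical(ds$files, ds2$files)
  expect_identical(ds$labels, ds2$labels)

  unlink(file.path(root, "Moderate"), recursive = TRUE)
  expect_error(load_labeled_dataset(root), class = "mrigrade_validation_error")
})

test_that("stratified_split sizes follow round-half-up per class, disjoint and covering", {
  ds <- generate_dataset(10, 32, noise_sd = 0, seed = 3)
  sp <- stratified_split(ds, 0.7, seed = 11)
  expect_equal(as.vector(table(sp$train$labels)), rep(7L, 4))
  expect_equal(as.vector(table(sp$test$labels)), rep(3L, 4))
  expect_length(sp$train, 28)
  expect_length(sp$test, 12)

  # reproducibility
  sp2 <- stratified_split(ds, 0.7, seed = 11)
  expect_identical(sp$train$labels, sp2$train$labels)
  expect_identical(
    vapply(sp$train$images, function(m) sum(m), numeric(1)),
    vapply(sp2$train$images, function(m) sum(m), numeric(1)))

  # fraction 0.5 with 2 per class -> 1/1
  ds2 <- generate_dataset(2, 32, noise_sd = 0, seed = 4)
  sp3 <- stratified_split(ds2, 0.5, seed = 1)
  expect_equal(as.vector(table(sp3$train$labels)), rep(1L, 4))
  expect_equal(as.vector(table(sp3$test$labels)), rep(1L, 4))
})
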