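# Reading, writing, resizing and loading class-labelled image directories.

#' Read an image file as a grayscale intensity matrix
#'
#' Decodes a PNG file and returns a numeric matrix with intensities in
#' `[0, 1]`. Colour images are collapsed to luminance with the ITU-R BT.601
#' weights (0.2989, 0.5870, 0.1140); an alpha channel, if present, is
#' discarded. PNG samples are already scaled by the bit-depth maximum on
#' decoding, so an 8-bit pixel value of 255 maps to 1.
#'
#' @param path path to a PNG file.
#' @return numeric matrix (rows = image rows, top first).
#' @seealso [write_image()], [load_labeled_dataset()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read image: '%s' does not exist", path))
  raw <- tryCatch(png::readPNG(path), error = function(e) {
    abort_io(sprintf("cannot decode '%s': %s", path, conditionMessage(e)))
  })
  img <- if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3L]
    if (nc >= 3L) {
      # BT.601 luminance, normalized so the weights sum to exactly 1
      w <- c(0.2989, 0.5870, 0.1140) / sum(c(0.2989, 0.5870, 0.1140))
      w[1L] * raw[, , 1L] + w[2L] * raw[, , 2L] + w[3L] * raw[, , 3L]
    } else {
      raw[, , 1L]  # gray + alpha
    }
  } else {
    raw
  }
  if (length(img) == 0L) abort_validation(sprintf("zero-sized image: '%s'", path))
  img <- pmin(pmax(img, 0), 1)
  img
}

#' Write a grayscale image to an 8-bit PNG file
#'
#' @param img grayscale image matrix in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_gray_image(img)
  png::writePNG(img, path)
  invisible(path)
}

#' Resize a grayscale image by bilinear interpolation
#'
#' Output pixel centres are mapped to input coordinates with the half-pixel
#' convention, so resizing to the original size reproduces the image exactly.
#' Results are clipped to `[0, 1]`.
#'
#' @param img grayscale image matrix.
#' @param size integer vector `c(rows, cols)` of the target dimensions, or a
#'   single integer for a square target.
#' @return resized image matrix.
#' @export
rescale <- function(img, size) {
  assert_gray_image(img)
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  if (any(size < 8L)) abort_validation("target dimensions must be at least 8 pixels")
  h <- nrow(img); w <- ncol(img)
  if (size[1L] == h && size[2L] == w) return(img)
  # input coordinate of each output pixel centre (0-based)
  ry <- (seq_len(size[1L]) - 0.5) * h / size[1L] - 0.5
  rx <- (seq_len(size[2L]) - 0.5) * w / size[2L] - 0.5
  ry <- pmin(pmax(ry, 0), h - 1)
  rx <- pmin(pmax(rx, 0), w - 1)
  y0 <- pmin(floor(ry), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(rx), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- ry - y0; fx <- rx - x0
  # outer-product weights over the 4 corner grids
  g <- function(yi, xi) img[cbind(rep(yi + 1L, times = length(xi)),
                                  rep(xi + 1L, each = length(yi)))]
  dim_out <- c(size[1L], size[2L])
  m00 <- matrix(g(y0, x0), dim_out[1L], dim_out[2L])
  m01 <- matrix(g(y0, x1), dim_out[1L], dim_out[2L])
  m10 <- matrix(g(y1, x0), dim_out[1L], dim_out[2L])
  m11 <- matrix(g(y1, x1), dim_out[1L], dim_out[2L])
  wy <- matrix(fy, dim_out[1L], dim_out[2L])
  wx <- matrix(fx, dim_out[1L], dim_out[2L], byrow = TRUE)
  out <- (1 - wy) * ((1 - wx) * m00 + wx * m01) + wy * ((1 - wx) * m10 + wx * m11)
  pmin(pmax(out, 0), 1)
}

#' Load a class-labelled image dataset from a directory tree
#'
#' Expects `root/<ClassName>/*.png` with exactly the four severity class
#' directories, by default `NonDemented`, `VeryMild`, `Mild`, `Moderate`
#' (labels 1 to 4 in that order). Files are read in lexicographic filename
#' order for platform-independent reproducibility.
#'
#' @param root dataset root directory.
#' @param class_names ordered character vector of class directory names.
#' @return a `labeled_dataset`: list with `images` (list of matrices),
#'   `labels` (integer vector, 1-based class indices) and `class_names`.
#' @export
load_labeled_dataset <- function(root, class_names = severity_class_names()) {
  if (!dir.exists(root)) abort_validation(sprintf("dataset root '%s' does not exist", root))
  missing <- class_names[!dir.exists(file.path(root, class_names))]
  if (length(missing) > 0L) {
    abort_validation(sprintf("missing class directories: %s", paste(missing, collapse = ", ")))
  }
  images <- list(); labels <- integer(0); files <- character(0)
  for (ci in seq_along(class_names)) {
    fs <- list.files(file.path(root, class_names[ci]), pattern = "\\.png$",
                     full.names = TRUE, ignore.case = TRUE)
    fs <- fs[order(basename(fs), method = "radix")]
    if (length(fs) == 0L) {
      abort_validation(sprintf("class directory '%s' contains no PNG images", class_names[ci]))
    }
    for (f in fs) {
      images[[length(images) + 1L]] <- read_image(f)
      labels <- c(labels, ci)
      files <- c(files, f)
    }
  }
  new_labeled_dataset(images, labels, class_names, files = files)
}

new_labeled_dataset <- function(images, labels, class_names = severity_class_names(),
                                files = NULL) {
  stopifnot(length(images) == length(labels))
  structure(list(images = images, labels = as.integer(labels),
                 class_names = class_names, files = files),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$images)

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d images, %d classes\n", length(x), length(x$class_names)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names), labels = x$class_names))
  print(tab)
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  new_labeled_dataset(ds$images[idx], ds$labels[idx], ds$class_names,
                      files = if (!is.null(ds$files)) ds$files[idx])
}

#' Stratified train/test split of a labelled dataset
#'
#' Per class, `round(train_fraction * class size)` images (round half up, so
#' the remainder of an exact half goes to the training side) are drawn into
#' the training set; the rest form the test set. The split is reproducible
#' given `seed`.
#'
#' @param ds a `labeled_dataset`.
#' @param train_fraction proportion of each class assigned to training.
#' @param seed integer seed for the class-wise sampling.
#' @return list with elements `train` and `test`, both `labeled_dataset`s.
#' @export
stratified_split <- function(ds, train_fraction = 0.7, seed = 0L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_validation("train_fraction must be strictly between 0 and 1")
  }
  counts <- tabulate(ds$labels, nbins = length(ds$class_names))
  if (any(counts < 2L)) abort_validation("every class needs at least 2 images to split")
  train_idx <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(ds$class_names)) {
      idx <- which(ds$labels == ci)
      n_tr <- round_half_up(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # keep both sides nonempty
      train_idx <- c(train_idx, sort(sample(idx, n_tr)))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(length(ds)), train_idx)
  list(train = subset_dataset(ds, train_idx), test = subset_dataset(ds, test_idx))
}
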