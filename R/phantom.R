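# Synthetic four-class brain phantoms.
#
# Each phantom is a bright elliptical "brain" on a dark background with a
# mid-gray cortical rim and a dark central "ventricle". Severity is encoded
# by the two morphological markers of dementia progression: the ventricle
# grows and the cortical rim thins with increasing class. Nothing else about
# real MRI contrast is modelled.

#' Default per-class phantom morphology
#'
#' `ventricle_scale` is the ventricle semi-axis as a fraction of the brain
#' semi-axis (strictly increasing with severity); `cortex_thickness` is the
#' cortical rim thickness in pixels at the reference 64-pixel image size
#' (strictly decreasing).
#'
#' @return list with numeric vectors `ventricle_scale` and `cortex_thickness`,
#'   one entry per severity class 1..4.
#' @export
phantom_class_params <- function() {
  list(
    ventricle_scale = c(0.12, 0.20, 0.30, 0.42),
    cortex_thickness = c(7.0, 5.5, 4.0, 2.5)
  )
}

#' Generate one synthetic brain phantom
#'
#' @param size image side length in pixels (square output), at least 32.
#' @param severity severity class in 1..4.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity units); the result is clipped to `[0, 1]`.
#' @param seed integer seed; identical spec + seed gives identical images.
#' @param center optional centre `c(row, col)` in pixels (defaults to the
#'   image centre).
#' @param rotation in-plane rotation of the brain ellipse, radians.
#' @param scale overall size multiplier of the brain ellipse.
#' @param params per-class morphology, see [phantom_class_params()].
#' @return grayscale image matrix in `[0, 1]`.
#' @export
generate_phantom <- function(size = 64L, severity = 1L, noise_sd = 0.05,
                             seed = 0L, center = NULL, rotation = 0,
                             scale = 1, params = phantom_class_params()) {
  size <- as.integer(size)
  if (is.na(size) || size < 32L) abort_validation("phantom size must be at least 32 pixels")
  if (!severity %in% 1:4) abort_validation("severity must be in 1..4")
  if (noise_sd < 0) abort_validation("noise_sd must be nonnegative")
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)

  # brain semi-axes: slightly anisotropic ellipse filling ~80% of the frame
  a <- 0.40 * size * scale   # column (horizontal) semi-axis
  b <- 0.33 * size * scale   # row (vertical) semi-axis
  vscale <- params$ventricle_scale[severity]
  cortex_px <- params$cortex_thickness[severity] * size / 64

  rows <- matrix(seq_len(size), size, size) - center[1L]
  cols <- matrix(seq_len(size), size, size, byrow = TRUE) - center[2L]
  ct <- cos(rotation); st <- sin(rotation)
  u <- ct * cols + st * rows    # rotated ellipse frame
  v <- -st * cols + ct * rows
  r2 <- (u / a)^2 + (v / b)^2

  img <- matrix(0.05, size, size)              # background
  inner <- 1 - cortex_px / min(a, b)           # rim -> interior transition
  inner <- max(inner, 0.05)
  img[r2 <= 1] <- 0.55                         # mid-gray cortical rim
  img[r2 <= inner^2] <- 0.85                   # bright parenchyma
  rv2 <- (u / (vscale * a))^2 + (v / (vscale * b))^2
  img[rv2 <= 1 & r2 <= inner^2] <- 0.15        # dark central ventricle

  if (noise_sd > 0) {
    img <- with_seed(seed, img + matrix(stats::rnorm(size * size, 0, noise_sd), size, size))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a balanced four-class phantom dataset
#'
#' Draws per-image jitter (centre offset up to 5% of the image size,
#' rotation up to 10 degrees, scale within ±10%) from a single seeded
#' stream, so the whole dataset is reproducible from one seed.
#'
#' @param n_per_class images per severity class.
#' @param size image side length in pixels.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param seed integer seed.
#' @return a `labeled_dataset` of `4 * n_per_class` phantoms, labels 1..4.
#' @export
generate_dataset <- function(n_per_class = 50L, size = 64L, noise_sd = 0.05,
                             seed = 0L) {
  n_per_class <- as.integer(n_per_class)
  if (is.na(n_per_class) || n_per_class < 1L) {
    abort_validation("n_per_class must be at least 1")
  }
  images <- vector("list", 4L * n_per_class)
  labels <- integer(4L * n_per_class)
  i <- 0L
  with_seed(seed, {
    for (sev in 1:4) {
      for (k in seq_len(n_per_class)) {
        i <- i + 1L
        jit <- stats::runif(4L)
        ctr <- (size + 1) / 2 + (jit[1:2] - 0.5) * 0.10 * size
        rot <- (jit[3L] - 0.5) * 2 * (10 * pi / 180)
        scl <- 1 + (jit[4L] - 0.5) * 0.2
        img_seed <- stats::runif(1L) * (.Machine$integer.max - 1)
        images[[i]] <- generate_phantom(size, sev, noise_sd, seed = img_seed,
                                        center = ctr, rotation = rot, scale = scl)
        labels[i] <- sev
      }
    }
  })
  new_labeled_dataset(images, labels)
}
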