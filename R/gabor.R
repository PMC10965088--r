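# Gabor filter bank features.

#' Specification of a Gabor filter bank
#'
#' The discrete even/odd kernel pair at frequency `f` (cycles/pixel) and
#' orientation `theta` (radians) is
#' \deqn{G_c(i,j) = B \exp(-(i^2+j^2)/(2\sigma)) \cos(2\pi f (i\cos\theta + j\sin\theta))}
#' \deqn{G_s(i,j) = C \exp(-(i^2+j^2)/(2\sigma)) \sin(2\pi f (i\cos\theta + j\sin\theta))}
#' with the normalizing factors `B` and `C` chosen so each kernel has unit
#' L2 norm. Here `i` is the horizontal and `j` the vertical (downward) kernel
#' coordinate.
#'
#' @param frequencies spatial frequencies in cycles/pixel.
#' @param orientations orientations in radians.
#' @param sigma Gaussian envelope parameter (appears as `2*sigma` in the
#'   exponent's denominator), pixels.
#' @param kernel_halfwidth kernel support half-width `h` (support
#'   `(-h..h)^2`), pixels.
#' @return a `gabor_spec` list.
#' @export
gabor_spec <- function(frequencies = c(0.1, 0.25),
                       orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                       sigma = 2, kernel_halfwidth = 7L) {
  if (any(frequencies <= 0)) abort_validation("gabor frequencies must be positive")
  if (sigma <= 0) abort_validation("gabor sigma must be positive")
  if (kernel_halfwidth < 1) abort_validation("kernel_halfwidth must be >= 1")
  structure(list(frequencies = frequencies, orientations = orientations,
                 sigma = sigma, kernel_halfwidth = as.integer(kernel_halfwidth)),
            class = "gabor_spec")
}

#' Even/odd Gabor kernel pair
#'
#' @param spec a [gabor_spec()].
#' @param f frequency, cycles/pixel.
#' @param theta orientation, radians.
#' @return list with matrices `even` (cosine kernel) and `odd` (sine
#'   kernel), each normalized to unit L2 norm, plus the factors `B` and `C`.
#' @export
gabor_kernel <- function(spec = gabor_spec(), f = 0.1, theta = 0) {
  h <- spec$kernel_halfwidth
  ii <- matrix(-h:h, 2 * h + 1, 2 * h + 1, byrow = TRUE)  # horizontal coord
  jj <- matrix(-h:h, 2 * h + 1, 2 * h + 1)                # vertical coord
  env <- exp(-(ii^2 + jj^2) / (2 * spec$sigma))
  phase <- 2 * pi * f * (ii * cos(theta) + jj * sin(theta))
  gc_raw <- env * cos(phase)
  gs_raw <- env * sin(phase)
  B <- 1 / sqrt(sum(gc_raw^2))
  ns <- sqrt(sum(gs_raw^2))
  C <- if (ns > 0) 1 / ns else 1
  list(even = B * gc_raw, odd = C * gs_raw, B = B, C = C)
}

# 2-D "same"-size correlation with reflect padding (kernel applied as a
# sliding window; kernels here are used directly, not flipped)
conv2_reflect <- function(img, kernel) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  ridx <- c(rev(seq_len(kh)), seq_len(h), h - seq_len(kh) + 1L)
  cidx <- c(rev(seq_len(kw)), seq_len(w), w - seq_len(kw) + 1L)
  pad <- img[ridx, cidx, drop = FALSE]
  out <- matrix(0, h, w)
  for (a in seq_len(nrow(kernel))) {
    for (b in seq_len(ncol(kernel))) {
      kv <- kernel[a, b]
      if (kv != 0) out <- out + kv * pad[(a):(a + h - 1L), (b):(b + w - 1L)]
    }
  }
  out
}

#' Gabor bank features
#'
#' For each (frequency, orientation) pair the image is filtered with the
#' even and odd kernels (same-size output, reflect padding) and the feature
#' is the mean response magnitude `sqrt(rc^2 + rs^2)` over all pixels.
#'
#' @param img grayscale image matrix, at least as large as the kernel.
#' @param spec a [gabor_spec()].
#' @return named numeric vector, one feature per (f, theta) pair.
#' @export
gabor_features <- function(img, spec = gabor_spec()) {
  assert_gray_image(img)
  k <- 2 * spec$kernel_halfwidth + 1
  if (nrow(img) < k || ncol(img) < k) {
    abort_validation("image smaller than the Gabor kernel support")
  }
  out <- numeric(0)
  for (fi in seq_along(spec$frequencies)) {
    for (ti in seq_along(spec$orientations)) {
      ker <- gabor_kernel(spec, spec$frequencies[fi], spec$orientations[ti])
      rc <- conv2_reflect(img, ker$even)
      rs <- conv2_reflect(img, ker$odd)
      val <- mean(sqrt(rc^2 + rs^2))
      names(val) <- sprintf("gabor_f%d_t%d", fi, ti)
      out <- c(out, val)
    }
  }
  out
}
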