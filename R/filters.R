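# PCA-filter and ICA-filter image features: project non-overlapping image
# tiles on a single learned component and summarise the activations.

# vectorized non-overlapping patch x patch tiles as rows of a matrix
image_tiles <- function(img, patch) {
  assert_gray_image(img)
  patch <- as.integer(patch)
  if (patch < 1L) abort_validation("patch size must be >= 1")
  nr <- nrow(img) %/% patch
  nc <- ncol(img) %/% patch
  if (nr * nc < 2L) abort_validation("image must contain at least 2 non-overlapping tiles")
  tiles <- matrix(0, nr * nc, patch * patch)
  t_i <- 0L
  for (bi in seq_len(nr)) {
    for (bj in seq_len(nc)) {
      t_i <- t_i + 1L
      tiles[t_i, ] <- as.vector(img[((bi - 1L) * patch + 1L):(bi * patch),
                                    ((bj - 1L) * patch + 1L):(bj * patch)])
    }
  }
  tiles
}

#' PCA-filter feature
#'
#' Vectorizes the image's non-overlapping `patch x patch` tiles, centres
#' them, projects on the first principal axis of the tile covariance, and
#' returns the mean absolute score. Constant images give 0.
#'
#' @param img grayscale image matrix.
#' @param patch tile side length in pixels.
#' @param seed unused (kept for interface symmetry with
#'   [ica_filter_feature()], which is stochastic).
#' @return scalar feature (nonnegative).
#' @export
pca_filter_feature <- function(img, patch = 8L, seed = 0L) {
  tiles <- image_tiles(img, patch)
  centered <- sweep(tiles, 2L, colMeans(tiles))
  if (sum(centered^2) < 1e-24) return(0)
  sv <- svd(centered, nu = 0L, nv = 1L)
  scores <- centered %*% sv$v[, 1L]
  mean(abs(scores))
}

#' ICA-filter feature
#'
#' Estimates one independent component of the centred tile matrix with a
#' FastICA-style fixed-point iteration (tanh nonlinearity, whitened inputs,
#' at most 200 iterations, convergence tolerance 1e-4, seeded random start)
#' and returns the mean absolute activation. If the iteration does not
#' converge the [pca_filter_feature()] value is returned instead.
#'
#' @param img grayscale image matrix.
#' @param patch tile side length in pixels.
#' @param seed integer seed for the random start.
#' @return scalar feature (nonnegative).
#' @export
ica_filter_feature <- function(img, patch = 8L, seed = 0L) {
  tiles <- image_tiles(img, patch)
  centered <- sweep(tiles, 2L, colMeans(tiles))
  if (sum(centered^2) < 1e-24) return(0)
  n <- nrow(centered)
  # whiten: keep components carrying non-negligible variance
  cv <- crossprod(centered) / (n - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-9)
  K <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(eg$values[keep]),
                                                 nrow = length(keep))
  z <- centered %*% K           # n x m, identity covariance
  m <- ncol(z)
  w <- with_seed(seed, stats::rnorm(m))
  w <- w / sqrt(sum(w^2))
  converged <- FALSE
  for (it in seq_len(200L)) {
    wx <- drop(z %*% w)
    gwx <- tanh(wx)
    gpwx <- 1 - gwx^2
    w_new <- drop(crossprod(z, gwx)) / n - mean(gpwx) * w
    w_new <- w_new / sqrt(sum(w_new^2))
    if (abs(abs(sum(w_new * w)) - 1) < 1e-4) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged) return(pca_filter_feature(img, patch, seed))
  mean(abs(drop(z %*% w)))
}
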