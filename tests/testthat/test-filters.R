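# PCA-filter and ICA-filter tile features.

test_that("pca_filter_feature matches the covariance eigen-decomposition oracle", {
  img <- random_image(32, 11)
  got <- pca_filter_feature(img, patch = 8L)
  # oracle: eigendecomposition of the tile covariance
  tiles <- mrigrade:::image_tiles(img, 8L)
  ctr <- sweep(tiles, 2, colMeans(tiles))
  v1 <- eigen(crossprod(ctr) / (nrow(ctr) - 1), symmetric = TRUE)$vectors[, 1]
  want <- mean(abs(ctr %*% v1))
  expect_equal(got, want, tolerance = 1e-9)

  expect_equal(pca_filter_feature(matrix(0.6, 32, 32)), 0)
  expect_gte(pca_filter_feature(random_image(16, 2), 8L), 0)
  expect_error(pca_filter_feature(matrix(0.5, 8, 8), patch = 8L),
               class = "mrigrade_validation_error")
})

test_that("ica_filter_feature is deterministic, zero on constants, and recovers a planted source", {
  img <- random_image(32, 21)
  a <- ica_filter_feature(img, 8L, seed = 5)
  b <- ica_filter_feature(img, 8L, seed = 5)
  expect_identical(a, b)
  expect_equal(ica_filter_feature(matrix(0.2, 32, 32)), 0)

  # two independent sources mixed across tile pixels: the estimated
  # activation must correlate strongly with one source
  set.seed(99)
  n_tiles <- 64
  s1 <- sign(rnorm(n_tiles))          # heavy-tailed/non-Gaussian
  s2 <- sign(rnorm(n_tiles))
  mix <- cbind(s1 + 0.4 * s2, 0.4 * s1 - s2)
  patt <- matrix(rnorm(2 * 16), 2, 16)
  tiles <- mix %*% patt                # 64 tiles of 16 pixels
  tiles <- (tiles - min(tiles)) / diff(range(tiles))
  img2 <- matrix(0, 32, 32)
  ti <- 0
  for (bi in 1:8) for (bj in 1:8) {
    ti <- ti + 1
    img2[((bi - 1) * 4 + 1):(bi * 4), ((bj - 1) * 4 + 1):(bj * 4)] <- matrix(tiles[ti, ], 4, 4)
  }
  # re-run the package's fixed-point estimate and inspect the activations
  tl <- mrigrade:::image_tiles(img2, 4L)
  ctr <- sweep(tl, 2, colMeans(tl))
  cv <- crossprod(ctr) / (nrow(ctr) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-9)
  K <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(eg$values[keep]), length(keep))
  z <- ctr %*% K
  w <- mrigrade:::with_seed(1, stats::rnorm(ncol(z)))
  w <- w / sqrt(sum(w^2))
  for (it in 1:200) {
    wx <- drop(z %*% w); g <- tanh(wx)
    w_new <- drop(crossprod(z, g)) / nrow(z) - mean(1 - g^2) * w
    w_new <- w_new / sqrt(sum(w_new^2))
    if (abs(abs(sum(w_new * w)) - 1) < 1e-4) { w <- w_new; break }
    w <- w_new
  }
  act <- drop(z %*% w)
  expect_gt(max(abs(cor(act, s1)), abs(cor(act, s2))), 0.9)
})
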