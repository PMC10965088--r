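# PCA reduction and component selection.

test_that("rank-1 data yields a single nonzero eigenvalue and flat NCSE", {
  t_par <- seq(0, 1, length.out = 20)
  X <- cbind(2 * t_par + 1, -3 * t_par)   # points on a line in 2-D
  m <- pca_fit(X)
  expect_equal(m$eigenvalues[2], 0, tolerance = 1e-9)
  expect_equal(m$ncse, c(1, 1), tolerance = 1e-9)
  expect_equal(ncol(pca_transform(m, X, 1)), 1)
  # k = 1 retains all variance on rank-1 data
  expect_equal(var(drop(pca_transform(m, X, 1))), sum(m$eigenvalues),
               tolerance = 1e-9)
})

test_that("loadings are orthonormal and eigenvalues match a direct oracle (and prcomp)", {
  set.seed(10)
  X <- matrix(rnorm(20 * 6), 20, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2))
  m <- pca_fit(X)
  L <- m$loadings
  expect_equal(crossprod(L), diag(6), tolerance = 1e-9)

  # oracle: eigendecomposition of the standardized covariance
  Z <- scale(X)
  ev <- eigen(cov(Z), symmetric = TRUE)$values
  expect_equal(m$eigenvalues, pmax(ev, 0), tolerance = 1e-9)
  # independent package cross-check
  expect_equal(m$eigenvalues, unname(prcomp(X, scale. = TRUE)$sdev^2),
               tolerance = 1e-9)

  # score variances equal eigenvalues; full-k transform preserves distances
  Zk <- pca_transform(m, X, 6)
  expect_equal(unname(apply(Zk, 2, var)), m$eigenvalues, tolerance = 1e-6)
  expect_equal(as.matrix(dist(Zk)), as.matrix(dist(Z)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # reconstruction at k = d recovers the standardized data
  expect_equal(Zk %*% t(L), unclass(Z), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("select_k follows the NCSE curve and is monotone in the threshold", {
  m <- structure(list(ncse = cumsum(c(3, 1, 0, 0)) / 4,
                      eigenvalues = c(3, 1, 0, 0)), class = "pca_model")
  expect_equal(select_k(m, 1.0), 2L)
  expect_equal(select_k(m, 0.5), 1L)
  ths <- c(0.1, 0.5, 0.75, 0.9, 0.999, 1)
  ks <- vapply(ths, function(th) select_k(m, th), integer(1))
  expect_true(all(diff(ks) >= 0))

  expect_error(pca_fit(matrix(1, 1, 3)), class = "mrigrade_validation_error")
  expect_error(pca_transform(pca_fit(matrix(rnorm(20), 10, 2)),
                             matrix(rnorm(20), 10, 2), k = 3),
               class = "mrigrade_validation_error")
})

test_that("zero-variance columns are tolerated with scale 1", {
  set.seed(3)
  X <- cbind(rnorm(15), rep(2, 15), rnorm(15))
  m <- pca_fit(X)
  expect_equal(m$scales[2], 1)
  expect_true(all(is.finite(pca_transform(m, X, 3))))
})
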