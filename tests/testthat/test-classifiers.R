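# LDA, Gaussian naive Bayes, linear SVM.

test_that("LDA places the boundary at the midpoint of two spherical classes", {
  set.seed(21)
  X <- rbind(matrix(rnorm(100, -3, 1), 50, 2), matrix(rnorm(100, 3, 1), 50, 2))
  y <- rep(1:2, each = 50)
  m <- fit_lda(X, y, n_classes = 2)
  grid <- as.matrix(expand.grid(seq(-5, 5, 1), seq(-5, 5, 1)))
  pred <- predict(m, grid)
  nearer <- ifelse(rowSums((grid + 3)^2) < rowSums((grid - 3)^2), 1L, 2L)
  off_mid <- abs(rowSums(grid)) > 1          # skip near-boundary ties
  expect_true(all(pred[off_mid] == nearer[off_mid]))

  # cross-check against MASS::lda on well-conditioned data
  colnames(X) <- colnames(grid) <- c("f1", "f2")
  ml <- MASS::lda(X, grouping = factor(y))
  expect_equal(pred, as.integer(predict(ml, grid)$class))
})

test_that("LDA tolerates duplicated features via the ridge and errors on singleton classes", {
  b <- make_blobs(20, seed = 2)
  Xd <- cbind(b$X, b$X[, 1])
  m <- fit_lda(Xd, b$y)
  expect_gte(mean(predict(m, Xd) == b$y), 0.99)
})

test_that("LDA with identical class data falls back to the larger prior / lowest label", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(1:2, each = 10)
  Xeq <- rbind(X[1:10, ], X[1:10, ])          # both classes see the same data
  m <- fit_lda(Xeq, y, n_classes = 2)
  expect_true(all(predict(m, Xeq) == 1L))     # equal priors -> lowest label
  expect_error(fit_lda(X[c(1:10, 11), ], c(rep(1L, 10), 2L)),
               class = "mrigrade_validation_error")
})

test_that("Gaussian NB separates far classes, floors variances, and ignores duplicates' effect on argmax order", {
  X <- matrix(c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)), 40, 1)
  y <- rep(1:2, each = 20)
  m <- fit_gaussian_nb(X, y, n_classes = 2)
  expect_equal(predict(m, X), y)

  # zero-variance feature must not produce NaN posteriors
  Xz <- cbind(X, rep(1, 40))
  mz <- fit_gaussian_nb(Xz, y, n_classes = 2)
  expect_true(all(is.finite(predict(mz, Xz, type = "score"))))

  # cross-check posterior ranking against e1071::naiveBayes
  b <- make_blobs(15, seed = 9)
  mine <- fit_gaussian_nb(b$X, b$y)
  ref <- e1071::naiveBayes(b$X, factor(b$y))
  expect_equal(predict(mine, b$X), as.integer(predict(ref, b$X)))

  # duplicating a feature rescales all class likelihoods consistently:
  # decisions keep the same argmax ordering on clearly separated data
  Xd <- cbind(b$X, b$X[, 1])
  md <- fit_gaussian_nb(Xd, b$y)
  expect_equal(predict(md, Xd), predict(mine, b$X))
})

test_that("linear SVM separates separable data and honors the C/s^2 scaling equivalence", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, -2, 0.5), 20, 2), matrix(rnorm(40, 2, 0.5), 20, 2))
  y <- rep(1:2, each = 20)
  m <- fit_linear_svm(X, y, C = 1, n_classes = 2)
  expect_equal(predict(m, X), y)

  m_scaled <- fit_linear_svm(10 * X, y, C = 1 / 100, n_classes = 2)
  set.seed(31)
  grid <- matrix(rnorm(60), 30, 2) * 2
  expect_equal(predict(m_scaled, 10 * grid), predict(m, grid))

  # symmetric +-1 points: decision value ~0 at the origin
  Xs <- matrix(c(-1, 1), 2, 1)
  ms <- fit_linear_svm(cbind(Xs, 0 * Xs), c(1L, 2L), C = 10, n_classes = 2)
  dv <- attr(predict(ms$fit, matrix(c(0, 0), 1, 2), decision.values = TRUE),
             "decision.values")
  expect_lt(abs(dv[1, 1]), 1e-3)

  expect_error(fit_linear_svm(X, rep(1L, 40)), class = "mrigrade_validation_error")
})

test_that("every classifier separates well-spread four-class blobs", {
  b <- make_blobs(50, d = 3, sep = 10, seed = 123)
  expect_equal(mean(predict(fit_decision_tree(b$X, b$y, tree_spec(max_splits = 20)),
                            b$X) == b$y), 1)
  expect_equal(mean(predict(fit_knn(b$X, b$y, knn_spec(3, "euclidean")), b$X) == b$y), 1)
  expect_equal(mean(predict(fit_linear_svm(b$X, b$y), b$X) == b$y), 1)
  expect_gte(mean(predict(fit_lda(b$X, b$y), b$X) == b$y), 0.99)
  expect_gte(mean(predict(fit_gaussian_nb(b$X, b$y), b$X) == b$y), 0.99)
  en <- fit_ensemble(b$X, b$y, ensemble_spec("Bag", 15), seed = 1)
  expect_equal(mean(predict(en, b$X) == b$y), 1)
})
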