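# Principal component reduction of the feature matrix with selection by the
# normalized cumulative sum of eigenvalues (NCSE).

#' Fit a PCA model on a feature matrix
#'
#' Columns are z-score standardized (zero-variance columns get scale 1),
#' the sample covariance of the standardized data is eigendecomposed, and
#' loadings are sorted by decreasing eigenvalue. Tiny negative eigenvalues
#' are clamped to 0, and each loading column's sign is fixed so that its
#' largest-magnitude entry is positive.
#'
#' @param X numeric matrix, observations in rows (n >= 2).
#' @return a `pca_model`: list with `means`, `scales`, `loadings` (d x d),
#'   `eigenvalues` and `ncse` (normalized cumulative eigenvalue curve).
#' @export
pca_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) abort_validation("PCA needs at least 2 observations")
  means <- colMeans(X)
  scales <- apply(X, 2L, stats::sd)
  scales[!is.finite(scales) | scales < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, means), 2L, scales, "/")
  S <- stats::cov(Z)
  eg <- eigen(S, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  L <- eg$vectors
  for (j in seq_len(ncol(L))) {
    i_max <- which.max(abs(L[, j]))
    if (L[i_max, j] < 0) L[, j] <- -L[, j]
  }
  total <- sum(lambda)
  ncse <- if (total > 0) cumsum(lambda) / total else rep(1, length(lambda))
  ncse[length(ncse)] <- 1
  structure(list(means = means, scales = scales, loadings = L,
                 eigenvalues = lambda, ncse = ncse,
                 feature_names = colnames(X)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  d <- length(x$eigenvalues)
  k99 <- select_k(x, 0.99)
  cat(sprintf("<pca_model> %d features; %d components reach 99%% of variance\n", d, k99))
  invisible(x)
}

#' Project a feature matrix onto the leading principal components
#'
#' @param model a [pca_fit()] result.
#' @param X feature matrix with the same columns the model was fitted on.
#' @param k number of components to keep (1..d).
#' @return n x k matrix of component scores.
#' @export
pca_transform <- function(model, X, k = length(model$eigenvalues)) {
  X <- as.matrix(X)
  d <- length(model$eigenvalues)
  if (k < 1L || k > d) abort_validation(sprintf("k must be in 1..%d", d))
  if (ncol(X) != d) abort_validation("X has the wrong number of columns for this model")
  Z <- sweep(sweep(X, 2L, model$means), 2L, model$scales, "/")
  Z %*% model$loadings[, seq_len(k), drop = FALSE]
}

#' @export
predict.pca_model <- function(object, newdata, k = length(object$eigenvalues), ...) {
  pca_transform(object, newdata, k)
}

#' Smallest component count reaching a variance threshold
#'
#' @param model a `pca_model`.
#' @param threshold proportion of total variance in `(0, 1]`; the default
#'   0.999 treats the printed "100%" of a cumulative-variance curve as float
#'   roundoff.
#' @return integer component count.
#' @export
select_k <- function(model, threshold = 0.999) {
  if (threshold <= 0 || threshold > 1) abort_validation("threshold must be in (0, 1]")
  as.integer(which(model$ncse >= threshold - 1e-12)[1L])
}
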