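# k-nearest-neighbour classification with Euclidean or correlation distance.

#' Specification of a KNN classifier
#'
#' @param k neighbour count.
#' @param metric `"correlation"` (1 - Pearson r between feature vectors;
#'   the distance to or from a constant vector is defined as 1) or
#'   `"euclidean"`.
#' @return a `knn_spec` list.
#' @export
knn_spec <- function(k = 12L, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort_validation("k must be >= 1")
  structure(list(k = k, metric = metric), class = "knn_spec")
}

# pairwise distance matrix, rows of A vs rows of B
knn_distances <- function(A, B, metric) {
  if (metric == "euclidean") {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  } else {
    # correlation distance: centre and scale each row; constant rows are
    # marked and get distance 1 against everything
    scale_rows <- function(M) {
      ctr <- M - rowMeans(M)
      ss <- sqrt(rowSums(ctr^2))
      const <- ss < 1e-12
      ctr[const, ] <- 0
      ss[const] <- 1
      list(Z = ctr / ss, const = const)
    }
    za <- scale_rows(A); zb <- scale_rows(B)
    d <- 1 - tcrossprod(za$Z, zb$Z)
    d[za$const, ] <- 1
    d[, zb$const] <- 1
    pmax(d, 0)
  }
}

#' Classify test points by their k nearest training neighbours
#'
#' Majority vote of the `k` nearest training observations; distance ties are
#' broken towards the lower training index and vote ties towards the lowest
#' label.
#'
#' @param Xtrain,ytrain training features and integer labels 1..K.
#' @param Xtest test features.
#' @param spec a [knn_spec()].
#' @param n_classes number of classes.
#' @param type `"class"` for labels, `"score"` for vote fractions.
#' @return integer labels, or an n x K matrix of vote fractions.
#' @export
predict_knn <- function(Xtrain, ytrain, Xtest, spec = knn_spec(),
                        n_classes = max(ytrain), type = c("class", "score")) {
  type <- match.arg(type)
  Xtrain <- as.matrix(Xtrain); Xtest <- as.matrix(Xtest)
  if (spec$k > nrow(Xtrain)) abort_validation("k exceeds the number of training points")
  D <- knn_distances(Xtest, Xtrain, spec$metric)
  votes <- matrix(0, nrow(Xtest), n_classes)
  for (i in seq_len(nrow(Xtest))) {
    nb <- order(D[i, ], seq_len(ncol(D)))[seq_len(spec$k)]  # stable in train index
    votes[i, ] <- tabulate(ytrain[nb], nbins = n_classes) / spec$k
  }
  if (type == "score") return(votes)
  max.col(votes, ties.method = "first")
}

#' Fit-interface wrapper around [predict_knn()]
#'
#' Stores the training set so KNN exposes the same fit/predict surface as
#' the other classifiers.
#'
#' @inheritParams predict_knn
#' @return a `severity_knn` classifier.
#' @export
fit_knn <- function(Xtrain, ytrain, spec = knn_spec(), n_classes = max(ytrain)) {
  structure(list(kind = "knn", X = as.matrix(Xtrain), y = as.integer(ytrain),
                 spec = spec, n_classes = n_classes),
            class = c("severity_knn", "severity_classifier"))
}

#' @export
predict.severity_knn <- function(object, newdata, type = c("class", "score"), ...) {
  predict_knn(object$X, object$y, newdata, object$spec, object$n_classes,
              type = match.arg(type))
}

#' @export
print.severity_knn <- function(x, ...) {
  cat(sprintf("<severity_knn> k=%d, metric=%s, %d training points\n",
              x$spec$k, x$spec$metric, nrow(x$X)))
  invisible(x)
}
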