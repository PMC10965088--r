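# Linear discriminant analysis, Gaussian naive Bayes, and the linear SVM
# (delegated to e1071). All share the severity_classifier predict contract:
# predict(model, X, type = "class") -> integer labels 1..K,
# predict(model, X, type = "score") -> n x K score matrix (posteriors or
# vote/probability shares) whose row argmax is the predicted label.

#' Fit a pooled-covariance linear discriminant classifier
#'
#' Class scores are the usual linear discriminants with a shared
#' within-class covariance and empirical priors. A ridge of
#' `1e-6 * trace(S)/d` is added to the pooled covariance so duplicated or
#' constant features do not make it singular.
#'
#' @param X numeric feature matrix.
#' @param y integer labels 1..K; every class present needs >= 2 samples.
#' @param n_classes number of classes.
#' @return a `severity_lda` classifier.
#' @export
fit_lda <- function(X, y, n_classes = max(y)) {
  X <- as.matrix(X); y <- as.integer(y)
  classes <- sort(unique(y))
  if (any(tabulate(y, n_classes)[classes] < 2L)) {
    abort_validation("every class needs at least 2 samples for LDA")
  }
  d <- ncol(X)
  means <- matrix(0, n_classes, d)
  Sw <- matrix(0, d, d)
  for (cc in classes) {
    Xi <- X[y == cc, , drop = FALSE]
    means[cc, ] <- colMeans(Xi)
    ctr <- sweep(Xi, 2L, means[cc, ])
    Sw <- Sw + crossprod(ctr)
  }
  Sw <- Sw / (nrow(X) - length(classes))
  ridge <- 1e-6 * sum(diag(Sw)) / d
  Sw <- Sw + diag(max(ridge, 1e-12), d)
  Sinv <- solve(Sw)
  priors <- tabulate(y, n_classes) / length(y)
  structure(list(kind = "lda", means = means, Sinv = Sinv, priors = priors,
                 classes = classes, n_classes = n_classes),
            class = c("severity_lda", "severity_classifier"))
}

#' @export
predict.severity_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  scores <- matrix(-Inf, nrow(X), object$n_classes)
  for (cc in object$classes) {
    mu <- object$means[cc, ]
    wc <- object$Sinv %*% mu
    scores[, cc] <- X %*% wc - 0.5 * drop(crossprod(mu, wc)) + log(object$priors[cc])
  }
  if (type == "score") {
    # softmax over discriminants -> posterior-like shares
    m <- apply(scores, 1L, max)
    e <- exp(scores - m)
    e[!is.finite(e)] <- 0
    return(e / rowSums(e))
  }
  max.col(scores, ties.method = "first")
}

#' @export
print.severity_lda <- function(x, ...) {
  cat(sprintf("<severity_lda> %d classes, %d features\n",
              length(x$classes), ncol(x$means)))
  invisible(x)
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Independent per-feature Gaussian likelihoods per class with empirical
#' priors; per-class per-feature variances are floored at 1e-9 so
#' zero-variance features keep the log-posterior finite.
#'
#' @inheritParams fit_lda
#' @return a `severity_nb` classifier.
#' @export
fit_gaussian_nb <- function(X, y, n_classes = max(y)) {
  X <- as.matrix(X); y <- as.integer(y)
  classes <- sort(unique(y))
  d <- ncol(X)
  means <- vars <- matrix(0, n_classes, d)
  for (cc in classes) {
    Xi <- X[y == cc, , drop = FALSE]
    means[cc, ] <- colMeans(Xi)
    v <- if (nrow(Xi) > 1L) apply(Xi, 2L, stats::var) else rep(0, d)
    vars[cc, ] <- pmax(v, 1e-9)
  }
  priors <- tabulate(y, n_classes) / length(y)
  structure(list(kind = "naive_bayes", means = means, vars = vars,
                 priors = priors, classes = classes, n_classes = n_classes),
            class = c("severity_nb", "severity_classifier"))
}

#' @export
predict.severity_nb <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  logpost <- matrix(-Inf, nrow(X), object$n_classes)
  for (cc in object$classes) {
    mu <- object$means[cc, ]; v <- object$vars[cc, ]
    ll <- -0.5 * rowSums(sweep(sweep(X, 2L, mu)^2, 2L, v, "/")) -
      0.5 * sum(log(2 * pi * v))
    logpost[, cc] <- ll + log(object$priors[cc])
  }
  if (type == "score") {
    m <- apply(logpost, 1L, max)
    e <- exp(logpost - m)
    e[!is.finite(e)] <- 0
    return(e / rowSums(e))
  }
  max.col(logpost, ties.method = "first")
}

#' @export
print.severity_nb <- function(x, ...) {
  cat(sprintf("<severity_nb> %d classes, %d features\n",
              length(x$classes), ncol(x$means)))
  invisible(x)
}

#' Fit a linear support vector machine
#'
#' Multiclass classification by one-vs-one voting over the class pairs
#' (e1071's native scheme), linear kernel, cost `C`. Features are not
#' rescaled internally (`scale = FALSE`), so scaling all features by `s`
#' with cost `C/s^2` yields identical predictions.
#'
#' @inheritParams fit_lda
#' @param C regularization (cost) parameter.
#' @return a `severity_svm` classifier.
#' @export
fit_linear_svm <- function(X, y, C = 1, n_classes = max(y)) {
  X <- as.matrix(X); y <- as.integer(y)
  if (length(unique(y)) < 2L) abort_validation("SVM needs at least 2 classes")
  fit <- e1071::svm(X, factor(y, levels = seq_len(n_classes)),
                    kernel = "linear", cost = C, scale = FALSE,
                    probability = TRUE, tolerance = 1e-4)
  structure(list(kind = "svm", fit = fit, C = C, n_classes = n_classes,
                 classes = sort(unique(y))),
            class = c("severity_svm", "severity_classifier"))
}

#' @export
predict.severity_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (type == "class") {
    return(as.integer(as.character(predict(object$fit, X))))
  }
  pr <- attr(predict(object$fit, X, probability = TRUE), "probabilities")
  scores <- matrix(0, nrow(X), object$n_classes)
  scores[, as.integer(colnames(pr))] <- pr
  scores
}

#' @export
print.severity_svm <- function(x, ...) {
  cat(sprintf("<severity_svm> linear kernel, C=%g, %d support vectors\n",
              x$C, x$fit$tot.nSV))
  invisible(x)
}
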