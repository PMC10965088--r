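# Tree ensembles: bagging, multiclass AdaBoost (SAMME), and RUSBoost
# (SAMME with per-iteration random undersampling to the minority class).

#' Specification of a tree ensemble
#'
#' @param method `"AdaBoost"`, `"Bag"` or `"RUSBoost"`.
#' @param n_learners number of trees.
#' @param learning_rate boosting shrinkage in `(0, 1]` (ignored by Bag).
#' @param learner a [tree_spec()] for the weak learner.
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(method = c("AdaBoost", "Bag", "RUSBoost"),
                          n_learners = 50L, learning_rate = 0.1,
                          learner = tree_spec(max_splits = 10L)) {
  method <- match.arg(method)
  n_learners <- as.integer(n_learners)
  if (is.na(n_learners) || n_learners < 1L) abort_validation("n_learners must be >= 1")
  if (learning_rate <= 0 || learning_rate > 1) {
    abort_validation("learning_rate must be in (0, 1]")
  }
  structure(list(method = method, n_learners = n_learners,
                 learning_rate = learning_rate, learner = learner),
            class = "ensemble_spec")
}

#' Fit a tree ensemble
#'
#' * `Bag`: trees on full-size bootstrap resamples, plain majority vote.
#' * `AdaBoost`: discrete multiclass SAMME reweighting with the spec's
#'   learning rate.
#' * `RUSBoost`: SAMME in which each iteration first randomly undersamples
#'   every class to the minority-class count before fitting the tree (the
#'   boosting weights are still updated on the full sample).
#'
#' All resampling draws from the seeded stream, so fits are reproducible.
#'
#' @param X numeric feature matrix.
#' @param y integer labels 1..K.
#' @param spec an [ensemble_spec()].
#' @param seed integer seed for bootstraps/undersampling.
#' @param n_classes number of classes.
#' @param instrument optional function called once per boosting iteration
#'   with the training indices used (testing hook for the RUSBoost balance
#'   contract).
#' @return a `severity_ensemble` classifier.
#' @export
fit_ensemble <- function(X, y, spec = ensemble_spec(), seed = 0L,
                         n_classes = max(y), instrument = NULL) {
  X <- as.matrix(X); y <- as.integer(y)
  n <- nrow(X)
  trees <- list()
  alphas <- numeric(0)
  with_seed(seed, {
    if (spec$method == "Bag") {
      for (b in seq_len(spec$n_learners)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (!is.null(instrument)) instrument(idx)
        trees[[b]] <- fit_decision_tree(X[idx, , drop = FALSE], y[idx],
                                        spec$learner, n_classes = n_classes)
        alphas[b] <- 1
      }
    } else {
      w <- rep(1 / n, n)
      K <- n_classes
      for (b in seq_len(spec$n_learners)) {
        fit_idx <- seq_len(n)
        if (spec$method == "RUSBoost") {
          counts <- tabulate(y, n_classes)
          m <- min(counts[counts > 0L])
          fit_idx <- unlist(lapply(which(counts > 0L), function(cc) {
            pool <- which(y == cc)
            if (length(pool) > m) sample(pool, m) else pool
          }))
          fit_idx <- sort(fit_idx)
        }
        if (!is.null(instrument)) instrument(fit_idx)
        wf <- w[fit_idx] / sum(w[fit_idx])
        tr <- fit_decision_tree(X[fit_idx, , drop = FALSE], y[fit_idx],
                                spec$learner, weights = wf, n_classes = n_classes)
        pred <- predict(tr, X)
        miss <- pred != y
        err <- sum(w[miss])
        if (err <= 0) {                      # perfect learner: keep it, stop
          trees[[b]] <- tr
          alphas[b] <- spec$learning_rate * log((1 - 1e-10) / 1e-10) + log(K - 1)
          break
        }
        if (err >= 1 - 1 / K) {              # no better than chance: stop
          if (length(trees) == 0L) { trees[[1L]] <- tr; alphas[1L] <- 1 }
          break
        }
        alpha <- spec$learning_rate * (log((1 - err) / err) + log(K - 1))
        trees[[b]] <- tr
        alphas[b] <- alpha
        w <- w * exp(alpha * miss)
        w <- w / sum(w)
      }
    }
  })
  structure(list(kind = paste0("ensemble_", tolower(spec$method)),
                 trees = trees, alphas = alphas, spec = spec,
                 n_classes = n_classes, classes = sort(unique(y))),
            class = c("severity_ensemble", "severity_classifier"))
}

#' @export
predict.severity_ensemble <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  votes <- matrix(0, nrow(X), object$n_classes)
  for (b in seq_along(object$trees)) {
    pred <- predict(object$trees[[b]], X)
    votes[cbind(seq_len(nrow(X)), pred)] <-
      votes[cbind(seq_len(nrow(X)), pred)] + object$alphas[b]
  }
  shares <- votes / pmax(rowSums(votes), 1e-300)
  if (type == "score") return(shares)
  max.col(shares, ties.method = "first")
}

#' @export
print.severity_ensemble <- function(x, ...) {
  cat(sprintf("<severity_ensemble> %s, %d trees\n", x$spec$method,
              length(x$trees)))
  invisible(x)
}
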