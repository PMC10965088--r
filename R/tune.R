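# Randomised hyperparameter search with stratified cross-validation.

# stratified fold assignment, seeded by the caller's RNG state
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cc in unique(y)) {
    idx <- sample(which(y == cc))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# one random candidate spec per family, drawn from the documented grids
draw_candidate <- function(family) {
  switch(family,
    tree = list(spec = tree_spec(criterion = sample(c("twoing", "gini"), 1L),
                                 max_splits = sample(c(2L, 5L, 10L, 20L, 50L, 138L), 1L))),
    knn = list(spec = knn_spec(k = sample(1:30, 1L),
                               metric = sample(c("correlation", "euclidean"), 1L))),
    svm = list(C = 10^stats::runif(1L, -2, 2)),
    nb = list(),
    adaboost = ,
    bag = ,
    rusboost = list(spec = ensemble_spec(
      method = switch(family, adaboost = "AdaBoost", bag = "Bag", rusboost = "RUSBoost"),
      n_learners = sample(c(10L, 25L, 50L, 100L), 1L),
      learning_rate = sample(c(0.001, 0.01, 0.1, 0.5, 1), 1L),
      learner = tree_spec(max_splits = sample(c(5L, 10L, 20L, 50L), 1L)))),
    abort_validation(sprintf("unknown classifier family '%s'", family))
  )
}

fit_family <- function(family, X, y, cand, n_classes, seed = 0L) {
  switch(family,
    tree = fit_decision_tree(X, y, cand$spec, n_classes = n_classes),
    knn = fit_knn(X, y, cand$spec, n_classes = n_classes),
    svm = fit_linear_svm(X, y, C = cand$C, n_classes = n_classes),
    nb = fit_gaussian_nb(X, y, n_classes = n_classes),
    lda = fit_lda(X, y, n_classes = n_classes),
    adaboost = ,
    bag = ,
    rusboost = fit_ensemble(X, y, cand$spec, seed = seed, n_classes = n_classes)
  )
}

#' Randomised hyperparameter optimization with stratified CV
#'
#' Draws `budget` random candidates from the family's grid (decision tree:
#' criterion and maximum splits; KNN: k in 1..30 and metric; SVM: cost on a
#' log grid; naive Bayes: no tunables; ensembles: learner count, learning
#' rate and tree size) and scores each by 5-fold stratified cross-validated
#' misclassification rate. Returns the candidate with the lowest CV error
#' (ties towards the first drawn).
#'
#' @param X feature matrix.
#' @param y integer labels 1..K.
#' @param family one of `"tree"`, `"knn"`, `"svm"`, `"nb"`, `"adaboost"`,
#'   `"bag"`, `"rusboost"`.
#' @param budget number of candidates to evaluate (>= 1).
#' @param seed integer seed for candidate drawing and fold assignment.
#' @param n_folds cross-validation folds.
#' @return list with `candidate` (the winning hyperparameters), `cv_error`,
#'   and `evaluated` (data.frame of every candidate with its error).
#' @export
optimize_hyperparameters <- function(X, y, family, budget = 10L, seed = 0L,
                                     n_folds = 5L) {
  budget <- as.integer(budget)
  if (is.na(budget) || budget < 1L) abort_validation("budget must be >= 1")
  X <- as.matrix(X); y <- as.integer(y)
  n_classes <- max(y)
  if (family == "nb") budget <- 1L  # nothing to tune
  results <- vector("list", budget)
  with_seed(seed, {
    folds <- stratified_folds(y, n_folds)
    for (b in seq_len(budget)) {
      cand <- draw_candidate(family)
      errs <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < n_classes) { errs[f] <- NA; next }
        # infeasible candidates (e.g. k larger than the fold) score NA
        errs[f] <- tryCatch({
          fit <- fit_family(family, X[tr, , drop = FALSE], y[tr], cand,
                            n_classes, seed = derive_seed(seed, b * n_folds + f))
          pred <- predict(fit, X[!tr, , drop = FALSE])
          mean(pred != y[!tr])
        }, error = function(e) NA_real_)
      }
      cv <- mean(errs, na.rm = TRUE)
      results[[b]] <- list(candidate = cand,
                           cv_error = if (is.nan(cv)) Inf else cv)
    }
  })
  errors <- vapply(results, `[[`, numeric(1), "cv_error")
  best <- which.min(errors)              # ties -> first drawn
  list(candidate = results[[best]]$candidate,
       cv_error = errors[best],
       evaluated = data.frame(candidate = seq_len(budget), cv_error = errors))
}
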