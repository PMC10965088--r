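# Greedy axis-aligned decision tree with the CART twoing splitting rule
# (gini also available). Supports observation weights so the tree can act as
# the weak learner inside the boosting ensembles.

#' Specification of a decision tree
#'
#' @param criterion splitting criterion, `"twoing"` or `"gini"`.
#' @param max_splits maximum number of internal nodes.
#' @param min_leaf minimum observations per leaf.
#' @return a `tree_spec` list.
#' @export
tree_spec <- function(criterion = c("twoing", "gini"), max_splits = 138L,
                      min_leaf = 1L) {
  criterion <- match.arg(criterion)
  max_splits <- as.integer(max_splits)
  if (is.na(max_splits) || max_splits < 1L) abort_validation("max_splits must be >= 1")
  structure(list(criterion = criterion, max_splits = max_splits,
                 min_leaf = as.integer(min_leaf)),
            class = "tree_spec")
}

#' Twoing score of a candidate binary split
#'
#' For side proportions `P_L`, `P_R` and per-class conditional proportions
#' `p(c|L)`, `p(c|R)`:
#' \deqn{score = \frac{P_L P_R}{4} \left(\sum_c |p(c|L) - p(c|R)|\right)^2}
#' The score lies in `[0, 0.25]`; 0 when both sides carry identical class
#' mixtures, 0.25 for an even, perfectly class-separating split.
#'
#' @param left_counts,right_counts per-class counts (or weights) on each side.
#' @return scalar score.
#' @export
twoing_score <- function(left_counts, right_counts) {
  nl <- sum(left_counts); nr <- sum(right_counts)
  if (nl <= 0 || nr <= 0) abort_validation("both sides of a split must be nonempty")
  pl <- nl / (nl + nr); pr <- nr / (nl + nr)
  (pl * pr / 4) * sum(abs(left_counts / nl - right_counts / nr))^2
}

gini_gain <- function(left_counts, right_counts) {
  nl <- sum(left_counts); nr <- sum(right_counts)
  if (nl <= 0 || nr <= 0) abort_validation("both sides of a split must be nonempty")
  n <- nl + nr
  tot <- left_counts + right_counts
  imp <- function(cnt, s) 1 - sum((cnt / s)^2)
  imp(tot, n) - (nl / n) * imp(left_counts, nl) - (nr / n) * imp(right_counts, nr)
}

# Vectorized best-split search for one node. Returns NULL when no admissible
# split exists, else list(feature, threshold, score).
best_split <- function(X, y, w, n_classes, criterion, min_leaf) {
  n <- nrow(X)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    ord <- order(xj, method = "radix")
    xs <- xj[ord]; ys <- y[ord]; ws <- w[ord]
    # cumulative weighted class counts after each sorted observation
    cum <- matrix(0, n, n_classes)
    cum[cbind(seq_len(n), ys)] <- ws
    cum <- apply(cum, 2L, cumsum)
    tot <- cum[n, ]
    cut_ok <- which(diff(xs) > 0)            # split between distinct values
    if (min_leaf > 1L) {
      cut_ok <- cut_ok[cut_ok >= min_leaf & (n - cut_ok) >= min_leaf]
    }
    if (length(cut_ok) == 0L) next
    L <- cum[cut_ok, , drop = FALSE]
    R <- matrix(tot, length(cut_ok), n_classes, byrow = TRUE) - L
    nl <- rowSums(L); nr <- rowSums(R)
    scores <- if (criterion == "twoing") {
      pl <- nl / (nl + nr)
      (pl * (1 - pl) / 4) * rowSums(abs(L / nl - R / nr))^2
    } else {
      ntot <- nl + nr
      imp_parent <- 1 - sum((tot / sum(tot))^2)
      imp_parent - (nl / ntot) * (1 - rowSums((L / nl)^2)) -
        (nr / ntot) * (1 - rowSums((R / nr)^2))
    }
    i_best <- which.max(scores)              # ties -> first cut position
    if (is.null(best) || scores[i_best] > best$score + 1e-15) {
      k <- cut_ok[i_best]
      best <- list(feature = j, threshold = (xs[k] + xs[k + 1L]) / 2,
                   score = scores[i_best])
    }
  }
  if (!is.null(best) && best$score <= 1e-15) best <- NULL
  best
}

node_majority <- function(y, w, n_classes) {
  cw <- vapply(seq_len(n_classes), function(cc) sum(w[y == cc]), numeric(1))
  which.max(cw)  # ties -> lowest label index
}

#' Fit a twoing-rule decision tree
#'
#' Grows a binary tree greedily: at each step the frontier node whose best
#' split has the highest criterion score is split, until `max_splits`
#' internal nodes, purity, or `min_leaf` stops growth. Thresholds are
#' midpoints of consecutive distinct feature values. Leaves predict the
#' (weight-)majority class, ties resolved towards the lowest label index.
#'
#' @param X numeric feature matrix (n x d, n >= 2).
#' @param y integer class labels 1..K.
#' @param spec a [tree_spec()].
#' @param weights optional nonnegative observation weights.
#' @param n_classes number of classes (defaults to `max(y)`).
#' @return a `severity_tree` classifier.
#' @export
fit_decision_tree <- function(X, y, spec = tree_spec(), weights = NULL,
                              n_classes = max(y)) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) < 2L) abort_validation("decision tree needs at least 2 observations")
  if (is.null(weights)) weights <- rep(1, nrow(X))
  # nodes table grown breadth-first by best-first selection
  nodes <- list()
  new_node <- function(idx) {
    list(idx = idx, leaf = TRUE, feature = NA_integer_, threshold = NA_real_,
         left = NA_integer_, right = NA_integer_,
         class = node_majority(y[idx], weights[idx], n_classes),
         dist = {
           cw <- vapply(seq_len(n_classes), function(cc) sum(weights[idx][y[idx] == cc]),
                        numeric(1))
           if (sum(cw) > 0) cw / sum(cw) else rep(1 / n_classes, n_classes)
         })
  }
  nodes[[1L]] <- new_node(seq_len(nrow(X)))
  frontier <- c(1L)          # candidate leaves, examined in creation order
  n_internal <- 0L
  while (n_internal < spec$max_splits && length(frontier) > 0L) {
    # pick the frontier node with the best available split
    cands <- lapply(frontier, function(ni) {
      idx <- nodes[[ni]]$idx
      if (length(unique(y[idx])) < 2L || length(idx) < 2L * spec$min_leaf) return(NULL)
      best_split(X[idx, , drop = FALSE], y[idx], weights[idx], n_classes,
                 spec$criterion, spec$min_leaf)
    })
    has <- !vapply(cands, is.null, logical(1))
    if (!any(has)) break
    scores <- vapply(cands, function(s) if (is.null(s)) -Inf else s$score, numeric(1))
    pick <- which.max(scores)          # ties -> earliest created node
    ni <- frontier[pick]
    sp <- cands[[pick]]
    idx <- nodes[[ni]]$idx
    go_left <- X[idx, sp$feature] <= sp$threshold
    li <- length(nodes) + 1L; ri <- length(nodes) + 2L
    nodes[[li]] <- new_node(idx[go_left])
    nodes[[ri]] <- new_node(idx[!go_left])
    nodes[[ni]]$leaf <- FALSE
    nodes[[ni]]$feature <- sp$feature
    nodes[[ni]]$threshold <- sp$threshold
    nodes[[ni]]$left <- li
    nodes[[ni]]$right <- ri
    frontier <- c(frontier[-pick], li, ri)
    n_internal <- n_internal + 1L
  }
  nodes <- lapply(nodes, function(nd) { nd$idx <- NULL; nd })
  structure(list(kind = "decision_tree", nodes = nodes, n_classes = n_classes,
                 spec = spec, classes = sort(unique(y))),
            class = c("severity_tree", "severity_classifier"))
}

tree_predict_matrix <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  scores <- matrix(0, n, model$n_classes)
  for (i in seq_len(n)) {
    ni <- 1L
    while (!model$nodes[[ni]]$leaf) {
      nd <- model$nodes[[ni]]
      ni <- if (X[i, nd$feature] <= nd$threshold) nd$left else nd$right
    }
    scores[i, ] <- model$nodes[[ni]]$dist
  }
  scores
}

#' @export
predict.severity_tree <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  sc <- tree_predict_matrix(object, newdata)
  if (type == "score") return(sc)
  max.col(sc, ties.method = "first")
}

#' @export
print.severity_tree <- function(x, ...) {
  n_int <- sum(!vapply(x$nodes, `[[`, logical(1), "leaf"))
  cat(sprintf("<severity_tree> criterion=%s, %d internal nodes, %d leaves\n",
              x$spec$criterion, n_int, length(x$nodes) - n_int))
  invisible(x)
}
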