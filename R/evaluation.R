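# Multiclass evaluation: confusion matrices, per-class sensitivity and
# precision, accuracy, one-vs-rest ROC curves and AUC, and the ranked
# method-comparison table.

#' Confusion matrix of multiclass predictions
#'
#' Entry `(i, j)` counts observations of true class `i` predicted as class
#' `j`.
#'
#' @param y_true,y_pred integer labels in `1..n_classes`.
#' @param n_classes number of classes.
#' @param class_names optional dimnames.
#' @return `n_classes x n_classes` count matrix (rows = true).
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 4L,
                             class_names = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) abort_validation("label vectors differ in length")
  if (any(y_true < 1L | y_true > n_classes) || any(y_pred < 1L | y_pred > n_classes)) {
    abort_validation(sprintf("labels must lie in 1..%d", n_classes))
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names, pred = class_names)
  cm
}

#' Per-class sensitivity, precision, and overall accuracy
#'
#' Sensitivity (recall) of class `c` is the diagonal count over the row sum;
#' precision is the diagonal count over the column sum; accuracy is the
#' trace over the total. Empty rows or columns yield 0 with a warning.
#'
#' @param confusion square count matrix (rows = true classes).
#' @return list with `sensitivity`, `precision` (per-class vectors) and
#'   `accuracy`.
#' @export
per_class_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || any(cm < 0)) {
    abort_validation("confusion must be a square nonnegative count matrix")
  }
  n <- sum(cm)
  if (n == 0) abort_validation("confusion matrix is all zeros")
  rs <- rowSums(cm); cs <- colSums(cm)
  if (any(rs == 0) || any(cs == 0)) {
    warning("empty class row/column: the corresponding rate is reported as 0")
  }
  sens <- ifelse(rs > 0, diag(cm) / rs, 0)
  prec <- ifelse(cs > 0, diag(cm) / cs, 0)
  list(sensitivity = sens, precision = prec, accuracy = sum(diag(cm)) / n)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps a decision threshold over the unique positive-class scores in
#' descending order (tied scores grouped), accumulating the true- and
#' false-positive rates; the AUC is computed by the trapezoid rule. The
#' curve starts at (0, 0) and ends at (1, 1).
#'
#' @param y_true integer labels.
#' @param scores numeric score for the positive class, one per observation.
#' @param positive_class the label treated as positive.
#' @return list with `fpr`, `tpr` (ROC points) and `auc`.
#' @export
roc_auc <- function(y_true, scores, positive_class = 1L) {
  pos <- y_true == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    abort_validation("ROC needs both positive and negative observations")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp_end <- c(which(diff(s) != 0), length(s))   # last index of each tie group
  tp <- cumsum(p)[grp_end]
  fp <- cumsum(!p)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Evaluate a classifier's predictions into a full report
#'
#' @param y_true integer labels 1..K.
#' @param y_pred integer predicted labels.
#' @param scores optional n x K score matrix (for ROC/AUC per class).
#' @param n_classes number of classes.
#' @param class_names class names for the confusion matrix.
#' @param method optional method name carried into comparison tables.
#' @return an `evaluation_report`: confusion matrix, per-class sensitivity
#'   and precision, accuracy, and (with scores) one-vs-rest ROC and AUC per
#'   class.
#' @export
evaluate_predictions <- function(y_true, y_pred, scores = NULL, n_classes = 4L,
                                 class_names = severity_class_names(),
                                 method = "unknown") {
  cm <- confusion_matrix(y_true, y_pred, n_classes, class_names)
  pm <- per_class_metrics(cm)
  roc <- auc <- NULL
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    roc <- vector("list", n_classes)
    auc <- rep(NA_real_, n_classes)
    for (cc in seq_len(n_classes)) {
      if (any(y_true == cc) && any(y_true != cc)) {
        r <- roc_auc(y_true, scores[, cc], cc)
        roc[[cc]] <- r[c("fpr", "tpr")]
        auc[cc] <- r$auc
      }
    }
    names(auc) <- class_names
  }
  structure(list(method = method, confusion = cm, sensitivity = pm$sensitivity,
                 precision = pm$precision, accuracy = pm$accuracy,
                 roc = roc, auc = auc, n = sum(cm)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: accuracy %.3f on %d samples\n",
              x$method, x$accuracy, x$n))
  print(x$confusion)
  if (!is.null(x$auc)) {
    cat("AUC (one-vs-rest): ", paste(sprintf("%s %.3f", names(x$auc), x$auc),
                                     collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ranked comparison table of evaluated methods
#'
#' Methods are sorted by accuracy (descending). The headline AUC is the
#' Non-Demented (class 1) one-vs-rest AUC; the macro average over classes is
#' also reported.
#'
#' @param reports list of `evaluation_report` objects.
#' @return data.frame with method, accuracy, auc_normal, auc_macro.
#' @export
comparison_report <- function(reports) {
  if (length(reports) < 1L) abort_validation("at least one report is required")
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(method = r$method, accuracy = r$accuracy,
               auc_normal = if (!is.null(r$auc)) r$auc[1L] else NA_real_,
               auc_macro = if (!is.null(r$auc)) mean(r$auc, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$accuracy, df$method), , drop = FALSE]
  rownames(df) <- NULL
  df
}
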