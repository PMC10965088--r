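# Confusion matrices, per-class rates, ROC/AUC, comparison tables.

test_that("confusion_matrix counts true/predicted pairs and validates labels", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2))
  want <- matrix(0L, 4, 4)
  want[1, 1] <- 1L; want[1, 2] <- 1L; want[2, 2] <- 1L
  expect_equal(unname(cm), want)
  expect_equal(sum(cm), 3)

  perfect <- confusion_matrix(rep(1:4, 5), rep(1:4, 5))
  expect_equal(unname(perfect), diag(5L, 4))
  expect_error(confusion_matrix(c(1, 5), c(1, 1)),
               class = "mrigrade_validation_error")
})

test_that("per-class metrics reproduce the worked sensitivity/precision decompositions", {
  # a class of 300 with 19 + 11 misclassified into two others: recall 90%
  cm <- matrix(0, 4, 4)
  cm[2, ] <- c(19, 270, 11, 0)
  cm[1, ] <- c(286, 4, 10, 0)
  cm[3, ] <- c(4, 0, 290, 6)
  cm[4, ] <- c(0, 0, 0, 300)
  m <- per_class_metrics(cm)
  expect_equal(unname(m$sensitivity[2]), 0.90)
  # predicted column with 286 correct plus 19 + 4 from other classes
  expect_equal(unname(m$precision[1]), 286 / (286 + 19 + 4))
  expect_equal(round(100 * m$precision[1], 1), 92.6)

  ident <- diag(10, 4)
  mi <- per_class_metrics(ident)
  expect_true(all(mi$sensitivity == 1) && all(mi$precision == 1) && mi$accuracy == 1)

  # prevalence-weighted sensitivities sum to the accuracy (count identity)
  set.seed(2)
  yt <- sample(1:4, 200, TRUE); yp <- sample(1:4, 200, TRUE)
  cm2 <- confusion_matrix(yt, yp)
  m2 <- per_class_metrics(cm2)
  expect_equal(sum(m2$sensitivity * rowSums(cm2) / sum(cm2)), m2$accuracy)

  expect_error(per_class_metrics(matrix(0, 4, 4)),
               class = "mrigrade_validation_error")
})

test_that("ROC endpoints, degenerate orderings, and the Mann-Whitney identity hold", {
  y <- rep(c(1L, 2L), each = 5)
  sep <- c(10:6, 5:1)                      # class 1 scores strictly higher
  r <- roc_auc(y, sep, positive_class = 1L)
  expect_equal(r$auc, 1)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_equal(roc_auc(y, -sep, 1L)$auc, 0)

  # trapezoid AUC equals U / (n_pos * n_neg) on tie-free scores
  set.seed(33)
  yy <- sample(1:2, 50, TRUE, prob = c(0.4, 0.6))
  ss <- rnorm(50) + (yy == 1)
  r2 <- roc_auc(yy, ss, 1L)
  u <- sum(outer(ss[yy == 1], ss[yy != 1], ">")) +
    0.5 * sum(outer(ss[yy == 1], ss[yy != 1], "=="))
  expect_equal(r2$auc, u / (sum(yy == 1) * sum(yy != 1)), tolerance = 1e-12)
  # independent package cross-check
  expect_equal(r2$auc,
               as.numeric(pROC::auc(pROC::roc(yy == 1, ss, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-9)

  expect_error(roc_auc(rep(1L, 5), rnorm(5), 1L),
               class = "mrigrade_validation_error")
})

test_that("comparison_report ranks methods by accuracy regardless of insertion order", {
  mk <- function(method, acc) {
    structure(list(method = method, accuracy = acc,
                   auc = c(0.9, 0.8, 0.7, 0.6), n = 100), class = "evaluation_report")
  }
  tab <- comparison_report(list(mk("b", 0.8), mk("a", 0.9)))
  expect_equal(tab$method, c("a", "b"))
  tab2 <- comparison_report(list(mk("a", 0.9), mk("b", 0.8)))
  expect_equal(tab, tab2)
  one <- comparison_report(list(mk("only", 0.5)))
  expect_equal(nrow(one), 1)

  # CSV round trip preserves the fields
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  expect_equal(read.csv(f), tab, tolerance = 1e-12)
})

test_that("evaluate_predictions assembles a coherent report", {
  set.seed(9)
  y <- rep(1:4, each = 25)
  sc <- matrix(runif(400), 100, 4)
  sc[cbind(1:100, y)] <- sc[cbind(1:100, y)] + 1.5
  pred <- max.col(sc, ties.method = "first")
  rep_ <- evaluate_predictions(y, pred, sc)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(sum(rep_$confusion), 100)
  expect_true(all(rep_$auc > 0.9))
  expect_equal(rep_$accuracy, mean(pred == y))
})
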