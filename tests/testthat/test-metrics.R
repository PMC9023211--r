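test_that("confusion_matrix counts true-by-predicted cells", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), n_classes = 2)
  expect_equal(unclass(unname(cm)), matrix(c(1L, 0L, 1L, 2L), 2, 2),
               ignore_attr = TRUE)
  cm4 <- confusion_matrix(0:3, 0:3, n_classes = 4)
  expect_equal(unname(diag(cm4)), rep(1L, 4))
  expect_equal(sum(cm4), 4L)
  expect_equal(rownames(cm4),
               c("no tumor", "meningioma", "pituitary tumor", "glioma"))
  expect_error(confusion_matrix(integer(0), integer(0)), "non-empty")
  expect_error(confusion_matrix(c(0, 1), c(0, 1, 2), n_classes = 4), "length")
  expect_error(confusion_matrix(c(0, 4), c(0, 1), n_classes = 4), "\\[0, 4\\)")
})

test_that("the worked two-class report is exact", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), n_classes = 2)
  rep <- metrics_report(cm)
  pc <- rep$per_class
  expect_equal(pc$precision, c(1, 2 / 3))
  expect_equal(pc$recall, c(0.5, 1))
  expect_equal(pc$f1, c(2 / 3, 0.8))
  expect_equal(pc$accuracy_pct, c(75, 75))
  expect_equal(rep$overall_accuracy_pct, 75)
})

test_that("degenerate matrices are handled", {
  # perfect diagonal
  rep <- metrics_report(diag(c(5L, 3L, 2L, 4L)))
  expect_true(all(rep$per_class$precision == 1))
  expect_true(all(rep$per_class$recall == 1))
  expect_true(all(rep$per_class$f1 == 1))
  expect_equal(rep$overall_accuracy_pct, 100)

  # single-class matrix
  rep1 <- metrics_report(matrix(7L, 1, 1))
  expect_equal(rep1$per_class$precision, 1)
  expect_equal(rep1$per_class$recall, 1)
  expect_equal(rep1$overall_accuracy_pct, 100)

  # a class never predicted: zero denominator reports 0 with a warning
  cm <- matrix(c(2L, 1L, 0L, 0L), 2, 2)
  w <- capture_warnings(rep0 <- metrics_report(cm))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(rep0$per_class$precision[2], 0)
  expect_error(metrics_report(matrix(0L, 2, 2)), "at least one")
})

test_that("report matches caret and a sample-wise oracle on random matrices", {
  skip_if_not_installed("caret")
  set.seed(19)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, 4), K, K)
    # keep every row and column populated so no denominator is zero
    diag(cm) <- diag(cm) + 1L
    rep <- metrics_report(cm)
    ref <- caret::confusionMatrix(as.table(t(cm)))  # caret rows = predicted
    by_class <- as.matrix(ref$byClass)
    if (K == 2) {
      # caret collapses 2 classes to one positive-class row; build both
      pos <- ref$byClass
      neg <- caret::confusionMatrix(as.table(t(cm[2:1, 2:1])))$byClass
      by_class <- rbind(pos, neg)
    }
    expect_equal(rep$per_class$precision,
                 unname(ifelse(is.na(by_class[, "Precision"]), 0,
                               by_class[, "Precision"])), tolerance = 1e-12)
    expect_equal(rep$per_class$recall,
                 unname(by_class[, "Recall"]), tolerance = 1e-12)
    expect_equal(rep$per_class$f1,
                 unname(ifelse(is.na(by_class[, "F1"]), 0,
                               by_class[, "F1"])), tolerance = 1e-12)
    expect_equal(rep$overall_accuracy_pct,
                 100 * unname(ref$overall["Accuracy"]), tolerance = 1e-12)
    expect_equal(rep$per_class$accuracy_pct, 100 * ovr_accuracy_from_cm(cm),
                 tolerance = 1e-12)
  }
})

test_that("micro-averaged recall equals overall accuracy", {
  set.seed(29)
  for (i in 1:20) {
    cm <- matrix(rpois(16, 5) + 1L, 4, 4)
    rep <- metrics_report(cm)
    tp <- diag(cm)
    micro_recall <- sum(tp) / sum(rowSums(cm))
    expect_equal(rep$overall_accuracy_pct, 100 * micro_recall,
                 tolerance = 1e-12)
  }
})

test_that("permuting class labels permutes the per-class rows", {
  set.seed(31)
  cm <- matrix(rpois(16, 5) + 1L, 4, 4,
               dimnames = list(class_names(4), class_names(4)))
  perm <- c(3, 1, 4, 2)
  rep_a <- metrics_report(cm)
  rep_b <- metrics_report(cm[perm, perm])
  for (col in c("accuracy_pct", "precision", "recall", "f1")) {
    expect_equal(rep_b$per_class[[col]], rep_a$per_class[[col]][perm],
                 tolerance = 1e-12)
  }
  expect_equal(rep_b$overall_accuracy_pct, rep_a$overall_accuracy_pct)
})

test_that("evaluate, tidy and autoplot wire predictions into a report", {
  d <- generate_scores(n_per_class = 10, seed = 7)
  fit <- drc_train(d, train_config(epochs = 1, seed = 1))
  # a 1-epoch fit may never predict some class; the 0/0 warning is expected
  rep <- suppressWarnings(evaluate(fit, d))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(tidy(rep)), 4)
  expect_equal(sum(rep$confusion), nrow(d))
  gl <- glance(rep)
  expect_equal(gl$n, nrow(d))
  expect_true(gl$overall_accuracy_pct >= 0 && gl$overall_accuracy_pct <= 100)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_output(print(rep), "Overall accuracy")
})
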