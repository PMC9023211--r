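#' Confusion matrix of true vs. predicted labels
#'
#' Rows are true classes, columns predicted classes:
#' `counts[i, j]` is the number of samples with true class `i - 1`
#' predicted as class `j - 1`.
#'
#' @param y_true,y_pred Integer label vectors of equal length, values in
#'   `[0, K)`.
#' @param n_classes Number of classes `K` (default 4).
#' @param labels Optional class names for dimnames (default
#'   [class_names()]).
#' @return A `K x K` integer matrix of class `confusion_matrix`.
#' @examples
#' confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), n_classes = 2)
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 4L,
                             labels = class_names(n_classes)) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must be non-empty and of equal length",
         call. = FALSE)
  }
  for (v in list(y_true, y_pred)) {
    if (anyNA(v) || any(v < 0 | v >= n_classes | v != as.integer(v))) {
      stop("labels must be integers in [0, ", n_classes, ")", call. = FALSE)
    }
  }
  lev <- seq_len(n_classes) - 1L
  cm <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = labels, predicted = labels))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class classification report
#'
#' For each class `c`, with `TP = counts[c, c]`, `FP` the rest of column
#' `c`, `FN` the rest of row `c` and `TN` everything else:
#' one-vs-rest accuracy `(TP + TN) / total` (reported as a percentage),
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)` and their
#' harmonic mean F1 (unit fractions). A zero denominator yields 0 with a
#' warning. Overall accuracy is the trace over the total, as a percentage;
#' it equals micro-averaged recall.
#'
#' @param cm A [confusion_matrix()] (any square count matrix works).
#' @return A `metrics_report`: a list with `per_class` (a tibble with
#'   columns `class`, `class_name`, `accuracy_pct`, `precision`, `recall`,
#'   `f1`), `overall_accuracy_pct`, and the matrix `confusion`.
#' @examples
#' cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), n_classes = 2)
#' metrics_report(cm)
#' @export
metrics_report <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0)) {
    stop("`cm` must be a square non-negative count matrix", call. = FALSE)
  }
  total <- sum(cm)
  if (total == 0) stop("`cm` must contain at least one count", call. = FALSE)
  K <- nrow(cm)
  labs <- rownames(cm)
  if (is.null(labs)) labs <- class_names(K)
  safe_div <- function(num, den, what) {
    out <- numeric(length(num))
    ok <- den > 0
    out[ok] <- num[ok] / den[ok]
    if (any(!ok)) {
      warning("zero denominator for ", what, " of class ",
              paste(which(!ok) - 1L, collapse = ", "),
              "; reporting 0", call. = FALSE)
    }
    out
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  per_class <- tibble::tibble(
    class = seq_len(K) - 1L,
    class_name = labs,
    accuracy_pct = as.numeric(100 * (tp + tn) / total),
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1)
  )
  structure(
    list(per_class = per_class,
         overall_accuracy_pct = 100 * sum(tp) / total,
         confusion = cm),
    class = "metrics_report"
  )
}

#' Evaluate a fitted classifier on a labelled test set
#'
#' Convenience wrapper: predicts every row, builds the confusion matrix and
#' returns the full [metrics_report()].
#'
#' @param fit A `drc_fit`.
#' @param data A labelled score tibble.
#' @return A `metrics_report`.
#' @export
evaluate <- function(fit, data) {
  data <- validate_scores(data, fit$ansatz$n_classes)
  pred <- drc_predict(fit$params, data, fit$ansatz)
  metrics_report(confusion_matrix(data$label, pred,
                                  n_classes = fit$ansatz$n_classes))
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  pc <- x$per_class
  cat("Per-class metrics\n")
  wide <- max(nchar(pc$class_name), nchar("Classes"))
  fmt <- paste0("  %-", wide, "s  %7s  %9s  %7s  %8s\n")
  cat(sprintf(fmt, "Classes", "Acc.", "Precision", "Recall", "F1 score"))
  for (i in seq_len(nrow(pc))) {
    cat(sprintf(paste0("  %-", wide, "s  %6.2f%%  %9.4f  %7.4f  %8.4f\n"),
                pc$class_name[i], pc$accuracy_pct[i], pc$precision[i],
                pc$recall[i], pc$f1[i]))
  }
  cat(sprintf("Overall accuracy: %.2f%%\n", x$overall_accuracy_pct))
  invisible(x)
}
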