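#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted reuploading classifier
#'
#' Returns the per-epoch training trajectory as a tibble, one row per epoch
#' with the mean cross-entropy loss.
#'
#' @param x A `drc_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch` and `loss`.
#' @export
tidy.drc_fit <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' One-row summary of a fitted reuploading classifier
#'
#' @param x A `drc_fit`.
#' @param ... Unused.
#' @return A tibble with the circuit shape, parameter count, epoch count
#'   and first/final epoch losses.
#' @export
glance.drc_fit <- function(x, ...) {
  tibble::tibble(
    n_qubits = x$ansatz$n_qubits,
    n_layers = x$ansatz$n_layers,
    n_classes = x$ansatz$n_classes,
    n_params = n_params(x$ansatz),
    epochs = length(x$loss_history),
    first_loss = x$loss_history[1],
    final_loss = x$loss_history[length(x$loss_history)]
  )
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class tibble (`class`, `class_name`, `accuracy_pct`,
#'   `precision`, `recall`, `f1`).
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_class
}

#' @rdname tidy.metrics_report
#' @param ... Unused.
#' @return `glance()`: a one-row tibble with `overall_accuracy_pct`,
#'   `macro_f1` and `n` evaluated samples.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    overall_accuracy_pct = x$overall_accuracy_pct,
    macro_f1 = mean(x$per_class$f1),
    n = sum(x$confusion)
  )
}

#' Plot the training loss curve
#'
#' @param object A `drc_fit`.
#' @param ... Unused.
#' @return A ggplot of mean cross-entropy loss against epoch.
#' @export
autoplot.drc_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Epoch", y = "Mean cross-entropy loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Plot a confusion-matrix heatmap
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot tile map of the confusion counts (rows true, columns
#'   predicted).
#' @export
autoplot.metrics_report <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  title = "Confusion matrix") +
    ggplot2::theme_minimal()
}
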