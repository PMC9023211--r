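#' Training configuration
#'
#' Holds the hyperparameters of the mini-batch RMSProp run. The defaults are
#' the reference configuration used throughout the package: a 4-qubit,
#' 6-layer ansatz trained with learning rate 0.01, RMSProp, batch size 26
#' and 50 epochs. `rho` and `epsilon` are the standard RMSProp decay and
#' stabilizer; the last incomplete batch of an epoch is used, not dropped.
#'
#' @param n_qubits,n_layers,n_classes Circuit shape (see [ansatz_config()]).
#' @param learning_rate Step size per update (default 0.01).
#' @param batch_size Samples per gradient step (default 26).
#' @param epochs Number of passes over the training set (default 50).
#' @param seed Integer seed driving initialization and shuffling (default 1).
#' @param rho RMSProp decay of the squared-gradient average (default 0.9).
#' @param epsilon RMSProp denominator stabilizer (default 1e-8).
#' @param gradient `"parameter_shift"` (default) or `"finite_diff"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_qubits = 4L, n_layers = 6L, n_classes = 4L,
                         learning_rate = 0.01, batch_size = 26L,
                         epochs = 50L, seed = 1L, rho = 0.9, epsilon = 1e-8,
                         gradient = c("parameter_shift", "finite_diff")) {
  gradient <- match.arg(gradient)
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be positive", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be a positive integer", call. = FALSE)
  if (rho <= 0 || rho >= 1) stop("`rho` must be in (0, 1)", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  structure(
    list(n_qubits = as.integer(n_qubits), n_layers = as.integer(n_layers),
         n_classes = as.integer(n_classes), learning_rate = learning_rate,
         optimizer = "rmsprop", batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed), rho = rho,
         epsilon = epsilon, gradient = gradient),
    class = "train_config"
  )
}

#' @export
print.train_config <- function(x, ...) {
  cat("<train_config> ", x$n_qubits, " qubits x ", x$n_layers,
      " layers, ", x$n_classes, " classes\n",
      "  lr ", x$learning_rate, ", rmsprop (rho ", x$rho, ", eps ",
      x$epsilon, "), batch ", x$batch_size, ", ", x$epochs,
      " epochs, seed ", x$seed, ", ", x$gradient, " gradients\n", sep = "")
  invisible(x)
}

as_ansatz_config <- function(config) {
  ansatz_config(n_qubits = config$n_qubits, n_layers = config$n_layers,
                n_classes = config$n_classes)
}

#' One RMSProp update
#'
#' Maintains an exponential moving average `a` of the squared gradient and
#' scales each coordinate's step by its root:
#' `a <- rho * a + (1 - rho) * g^2`, then
#' `params <- params - lr * g / (sqrt(a) + epsilon)`.
#'
#' @param params Angle array.
#' @param grads Gradient array of the same shape.
#' @param state A list with `accumulator` (same shape, all entries >= 0) and
#'   `step_count`; pass `rmsprop_init(params)` for the first call.
#' @param config A [train_config()] (uses `learning_rate`, `rho`, `epsilon`).
#' @return A list with updated `params` and `state`.
#' @export
rmsprop_step <- function(params, grads, state, config) {
  if (!identical(dim(params), dim(grads)) ||
      !identical(dim(params), dim(state$accumulator))) {
    stop("`params`, `grads` and the accumulator must share a shape",
         call. = FALSE)
  }
  acc <- config$rho * state$accumulator + (1 - config$rho) * grads^2
  params <- params - config$learning_rate * grads / (sqrt(acc) + config$epsilon)
  list(params = params,
       state = list(accumulator = acc,
                    step_count = state$step_count + 1L))
}

#' @rdname rmsprop_step
#' @export
rmsprop_init <- function(params) {
  list(accumulator = array(0, dim = dim(params)), step_count = 0L)
}

#' Stratified train/test split of a score tibble
#'
#' Splits class by class: each class contributes `round(train_fraction * n)`
#' rows to the training set and the remainder to the test set, so a 70:30
#' split of balanced classes is exactly balanced on both sides. The split is
#' disjoint, exhaustive and deterministic given `seed`.
#'
#' @param data A labelled score tibble (see [generate_scores()]).
#' @param train_fraction Fraction per class assigned to training
#'   (default 0.7).
#' @param seed Integer RNG seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_scores <- function(data, train_fraction = 0.7, seed = 1L) {
  if (nrow(data) == 0L) stop("`data` must be non-empty", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  counts <- table(data$label)
  if (any(counts < 2)) {
    stop("every class needs at least 2 samples to split", call. = FALSE)
  }
  with_preserved_seed(seed, {
    idx_train <- unlist(lapply(names(counts), function(cls) {
      rows <- which(data$label == as.integer(cls))
      take <- round(train_fraction * length(rows))
      sample(rows, take)
    }))
  })
  idx_train <- sort(idx_train)
  list(train = data[idx_train, , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE])
}

#' Train the data-reuploading classifier
#'
#' Initializes every angle from uniform(-pi, pi), then runs mini-batch
#' RMSProp: each epoch shuffles the training rows, partitions them into
#' batches of `batch_size` (the final partial batch included), and applies
#' one [rmsprop_step()] per batch. The epoch's mean loss (sample-weighted
#' over its batches, evaluated at the parameters current when each batch
#' was visited) is recorded in `loss_history`. All randomness flows from
#' `config$seed`, so identical configs reproduce bitwise-identical results.
#'
#' @param data A labelled score tibble (training split).
#' @param config A [train_config()].
#' @param verbose If `TRUE`, logs one line per epoch (epoch, mean loss,
#'   training accuracy) to stderr.
#' @return An object of class `drc_fit`: a list with `params` (the trained
#'   angle array), `loss_history` (one mean loss per epoch), `config`, and
#'   the ansatz configuration `ansatz`.
#' @examples
#' \donttest{
#' d <- generate_scores(n_per_class = 30, seed = 7)
#' fit <- drc_train(d, train_config(epochs = 2, seed = 1))
#' fit$loss_history
#' }
#' @export
drc_train <- function(data, config = train_config(), verbose = FALSE) {
  if (!inherits(config, "train_config")) {
    stop("`config` must be a train_config", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("`data` must be non-empty", call. = FALSE)
  data <- validate_scores(data, config$n_classes)
  ansatz <- as_ansatz_config(config)
  n <- nrow(data)
  params <- init_params(ansatz, seed = config$seed)
  opt <- rmsprop_init(params)
  loss_history <- numeric(config$epochs)
  with_preserved_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      order <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        rows <- order[s:min(s + config$batch_size - 1L, n)]
        batch <- data[rows, , drop = FALSE]
        epoch_loss <- epoch_loss +
          length(rows) * cross_entropy_loss(params, batch, ansatz)
        g <- drc_gradient(params, batch, ansatz, method = config$gradient)
        upd <- rmsprop_step(params, g, opt, config)
        params <- upd$params
        opt <- upd$state
      }
      loss_history[epoch] <- epoch_loss / n
      if (verbose) {
        acc <- mean(drc_predict(params, data, ansatz) == data$label)
        message(sprintf("epoch %3d  loss %.5f  train acc %.3f",
                        epoch, loss_history[epoch], acc))
      }
    }
  })
  structure(
    list(params = params, loss_history = loss_history, config = config,
         ansatz = ansatz),
    class = "drc_fit"
  )
}

#' @export
print.drc_fit <- function(x, ...) {
  cat("<drc_fit> ", x$ansatz$n_qubits, "-qubit, ", x$ansatz$n_layers,
      "-layer reuploading classifier (", n_params(x$ansatz),
      " angles)\n", sep = "")
  cat(sprintf("  %d epochs; loss %.5f -> %.5f\n",
              length(x$loss_history), x$loss_history[1],
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predict classes or probabilities from a fitted classifier
#'
#' @param object A `drc_fit`.
#' @param new_data A tibble with score columns.
#' @param type `"class"` (default) adds a `.pred` column of class labels;
#'   `"prob"` adds `p0..p{K-1}` probability columns; `"both"` adds both.
#' @param ... Unused.
#' @return `new_data` with prediction columns appended.
#' @export
predict.drc_fit <- function(object, new_data,
                            type = c("class", "prob", "both"), ...) {
  type <- match.arg(type)
  out <- tibble::as_tibble(new_data)
  if (type %in% c("prob", "both")) {
    out <- dplyr::bind_cols(out, drc_probs(object$params, new_data,
                                           object$ansatz))
  }
  if (type %in% c("class", "both")) {
    out$.pred <- drc_predict(object$params, new_data, object$ansatz)
  }
  out
}
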