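#' Ansatz configuration for the data-reuploading classifier
#'
#' Describes the circuit topology: number of qubits, number of layers, number
#' of classes, and which qubits are measured for the class readout. The
#' default is the four-qubit, six-layer configuration used throughout: each
#' layer applies one three-parameter `Rot` gate per qubit (12 trainable
#' angles per layer, 72 in total) followed by the linear CNOT cascade
#' `0->1, 1->2, 2->3`, and the input scores are re-injected additively into
#' every rotation angle of every layer (the "data re-uploading" scheme).
#'
#' Readout: the joint Born distribution of the readout qubits is the class
#' distribution. Four classes read qubits `(0, 1)` (outcomes 00, 01, 10, 11
#' map to classes 0-3, qubit 0 being the more significant bit); two classes
#' read qubit 0 alone.
#'
#' @param n_qubits Number of qubits (>= 2; default 4).
#' @param n_layers Number of reuploading layers (default 6).
#' @param n_classes 4 or 2 (default 4).
#' @param readout_qubits Zero-based indices of measured qubits; defaults to
#'   the first `log2(n_classes)` qubits.
#' @return An object of class `ansatz_config`.
#' @examples
#' ansatz_config()
#' @export
ansatz_config <- function(n_qubits = 4L, n_layers = 6L, n_classes = 4L,
                          readout_qubits = NULL) {
  if (!n_classes %in% c(2L, 4L)) {
    stop("`n_classes` must be 2 or 4", call. = FALSE)
  }
  n_qubits <- as.integer(n_qubits)
  n_layers <- as.integer(n_layers)
  if (is.na(n_qubits) || n_qubits < 2L || n_qubits > MAX_QUBITS) {
    stop("`n_qubits` must be between 2 and ", MAX_QUBITS, call. = FALSE)
  }
  if (is.na(n_layers) || n_layers < 1L) {
    stop("`n_layers` must be a positive integer", call. = FALSE)
  }
  k <- as.integer(round(log2(n_classes)))
  if (is.null(readout_qubits)) readout_qubits <- seq_len(k) - 1L
  readout_qubits <- as.integer(readout_qubits)
  if (length(readout_qubits) != k || anyDuplicated(readout_qubits) ||
      any(readout_qubits < 0L | readout_qubits >= n_qubits)) {
    stop("`readout_qubits` must be ", k, " distinct indices in [0, ",
         n_qubits, ")", call. = FALSE)
  }
  structure(
    list(n_qubits = n_qubits, n_layers = n_layers, n_classes = n_classes,
         readout_qubits = readout_qubits),
    class = "ansatz_config"
  )
}

#' @export
print.ansatz_config <- function(x, ...) {
  cat("<ansatz_config> ", x$n_qubits, " qubits, ", x$n_layers,
      " layers, ", x$n_classes, " classes; ",
      n_params(x), " trainable angles (",
      params_per_layer(x), "/layer); readout qubits (",
      paste(x$readout_qubits, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Trainable parameter counts of an ansatz
#'
#' Each `Rot` gate carries three angles, one gate per qubit per layer, so a
#' layer exposes `3 * n_qubits` trainable parameters (12 in the default
#' four-qubit configuration) and the whole model `3 * n_qubits * n_layers`
#' (72 for six layers).
#'
#' @param config An [ansatz_config()].
#' @return Integer parameter count.
#' @export
params_per_layer <- function(config) {
  3L * config$n_qubits
}

#' @rdname params_per_layer
#' @export
n_params <- function(config) {
  config$n_layers * params_per_layer(config)
}

#' Initialize circuit parameters
#'
#' Draws every trainable angle independently from uniform(-pi, pi),
#' deterministically under `seed`.
#'
#' @param config An [ansatz_config()].
#' @param seed Integer RNG seed.
#' @return Numeric array of dim `(n_layers, n_qubits, 3)`; the third index
#'   runs over the `Rot` angles (phi, theta, omega).
#' @export
init_params <- function(config, seed = 1L) {
  with_preserved_seed(seed, {
    array(stats::runif(n_params(config), -pi, pi),
          dim = c(config$n_layers, config$n_qubits, 3L))
  })
}

check_params <- function(params, config) {
  want <- c(config$n_layers, config$n_qubits, 3L)
  if (!is.numeric(params) || !identical(dim(params), as.integer(want))) {
    stop("`params` must be a numeric array of dim (",
         paste(want, collapse = " x "), ")", call. = FALSE)
  }
  if (!all(is.finite(params))) {
    stop("`params` must be finite", call. = FALSE)
  }
  invisible(params)
}

# pad a score vector with zeros up to the qubit count (a 2-class score
# vector on the 4-qubit circuit leaves the trailing qubits data-free)
pad_x <- function(x, n_qubits) {
  if (length(x) > n_qubits) {
    stop("score vector longer than the qubit count", call. = FALSE)
  }
  c(x, rep(0, n_qubits - length(x)))
}

#' Apply one reuploading layer
#'
#' For each qubit `q` applies `Rot(angles[q,1] + pi*x[q], angles[q,2] +
#' pi*x[q], angles[q,3] + pi*x[q])`, then the CNOT cascade
#' `CNOT(0,1), CNOT(1,2), ...`. The additive `pi * x_q` term is the data
#' injection: the same input component enters all three angles of its
#' dedicated qubit, and every layer re-injects it.
#'
#' @param state A statevector.
#' @param layer_angles Numeric `(n_qubits x 3)` matrix of trainable angles.
#' @param x Numeric score vector (length `<= n_qubits`; shorter vectors are
#'   zero-padded).
#' @return The transformed statevector.
#' @export
build_layer <- function(state, layer_angles, x) {
  check_statevector(state)
  n <- n_qubits(state)
  if (!is.matrix(layer_angles) || nrow(layer_angles) != n ||
      ncol(layer_angles) != 3L || !all(is.finite(layer_angles))) {
    stop("`layer_angles` must be a finite (", n, " x 3) matrix", call. = FALSE)
  }
  x <- pad_x(x, n)
  for (q in seq_len(n) - 1L) {
    inj <- pi * x[q + 1L]
    g <- gate_rot(layer_angles[q + 1L, 1L] + inj,
                  layer_angles[q + 1L, 2L] + inj,
                  layer_angles[q + 1L, 3L] + inj)
    state <- apply_1q(state, g, q)
  }
  for (q in seq_len(n - 1L) - 1L) {
    state <- apply_cnot(state, q, q + 1L)
  }
  state
}

# does the config's readout allow the compiled leading-qubits kernel?
readout_is_leading <- function(config) {
  identical(config$readout_qubits,
            seq_along(config$readout_qubits) - 1L)
}

#' Class probabilities of the reuploading circuit
#'
#' Runs `|0...0>` through `n_layers` reuploading layers (re-injecting `x`
#' in every layer) and returns the Born-rule marginal of the readout
#' qubits: a probability vector over the `n_classes` classes.
#'
#' @param params Angle array from [init_params()] (dim
#'   `n_layers x n_qubits x 3`).
#' @param x Numeric score vector.
#' @param config An [ansatz_config()].
#' @param backend `"cpp"` (compiled kernel, default) or `"r"` (reference
#'   composition of [build_layer()] calls); both produce the same numbers.
#' @return Numeric probability vector of length `n_classes`, summing to 1.
#' @examples
#' cfg <- ansatz_config()
#' drc_forward(init_params(cfg, seed = 1), c(0.7, 0.1, 0.1, 0.1), cfg)
#' @export
drc_forward <- function(params, x, config = ansatz_config(),
                        backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  check_params(params, config)
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("`x` must be a finite numeric vector", call. = FALSE)
  }
  x <- pad_x(x, config$n_qubits)
  if (backend == "cpp" && readout_is_leading(config)) {
    p <- cpp_batch_probs(as.numeric(params), matrix(x, nrow = 1),
                         config$n_layers, config$n_qubits,
                         length(config$readout_qubits))
    return(as.numeric(p[1, ]))
  }
  state <- zero_state(config$n_qubits)
  for (l in seq_len(config$n_layers)) {
    state <- build_layer(state, matrix(params[l, , ], ncol = 3L), x)
  }
  marginal_probs(state, config$readout_qubits)
}

#' Class probabilities and predictions for a dataset
#'
#' `drc_probs()` evaluates the circuit on every row of a score tibble and
#' returns the per-class probabilities; `drc_predict()` returns the argmax
#' class (ties broken toward the lowest class index).
#'
#' @inheritParams drc_forward
#' @param data A tibble with score columns `s0..s{K-1}` (labels optional).
#' @return `drc_probs()`: a tibble with columns `p0..p{K-1}`;
#'   `drc_predict()`: an integer vector of class labels.
#' @export
drc_probs <- function(params, data, config = ansatz_config()) {
  check_params(params, config)
  cols <- score_cols(config$n_classes)
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("missing score columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(data[cols])
  if (ncol(X) < config$n_qubits) {
    X <- cbind(X, matrix(0, nrow(X), config$n_qubits - ncol(X)))
  }
  if (readout_is_leading(config)) {
    P <- cpp_batch_probs(as.numeric(params), X, config$n_layers,
                         config$n_qubits, length(config$readout_qubits))
  } else {
    P <- t(apply(X, 1, function(x) drc_forward(params, x, config,
                                               backend = "r")))
  }
  colnames(P) <- paste0("p", seq_len(config$n_classes) - 1L)
  tibble::as_tibble(P)
}

#' @rdname drc_probs
#' @export
drc_predict <- function(params, data, config = ansatz_config()) {
  P <- as.matrix(drc_probs(params, data, config))
  max.col(P, ties.method = "first") - 1L
}

#' Mean cross-entropy loss on a labelled batch
#'
#' Average over the batch of `-log(p_true)` with the true-class probability
#' clipped below at 1e-12, so the loss is finite and non-negative.
#'
#' @inheritParams drc_probs
#' @param data A tibble with score columns and an integer `label` column.
#' @return A single non-negative number.
#' @export
cross_entropy_loss <- function(params, data, config = ansatz_config()) {
  check_params(params, config)
  if (nrow(data) == 0L) {
    stop("`data` must contain at least one row", call. = FALSE)
  }
  if (!"label" %in% names(data) ||
      any(data$label < 0 | data$label >= config$n_classes)) {
    stop("`data` must carry labels in [0, ", config$n_classes, ")",
         call. = FALSE)
  }
  X <- as.matrix(data[score_cols(config$n_classes)])
  if (ncol(X) < config$n_qubits) {
    X <- cbind(X, matrix(0, nrow(X), config$n_qubits - ncol(X)))
  }
  cpp_batch_loss(as.numeric(params), X, as.integer(data$label),
                 config$n_layers, config$n_qubits,
                 length(config$readout_qubits))
}

#' Gradient of the cross-entropy loss
#'
#' Two interchangeable methods: the exact parameter-shift rule (each angle
#' parameterizes one rotation with generator eigenvalues of half-integer
#' spacing, so evaluating the circuit at +/- pi/2 shifts gives the exact
#' derivative of each probability, combined with the chain rule through the
#' loss), and central finite differences on the batch loss with step `h`.
#' The two agree to about 1e-5; parameter-shift is the default.
#'
#' @inheritParams cross_entropy_loss
#' @param method `"parameter_shift"` or `"finite_diff"`.
#' @param h Step for finite differences (default 1e-6).
#' @return Numeric array shaped like `params`.
#' @export
drc_gradient <- function(params, data, config = ansatz_config(),
                         method = c("parameter_shift", "finite_diff"),
                         h = 1e-6) {
  method <- match.arg(method)
  check_params(params, config)
  if (nrow(data) == 0L) {
    stop("`data` must contain at least one row", call. = FALSE)
  }
  if (!"label" %in% names(data) ||
      any(data$label < 0 | data$label >= config$n_classes)) {
    stop("`data` must carry labels in [0, ", config$n_classes, ")",
         call. = FALSE)
  }
  X <- as.matrix(data[score_cols(config$n_classes)])
  if (ncol(X) < config$n_qubits) {
    X <- cbind(X, matrix(0, nrow(X), config$n_qubits - ncol(X)))
  }
  y <- as.integer(data$label)
  k <- length(config$readout_qubits)
  g <- if (method == "parameter_shift") {
    cpp_grad_pshift(as.numeric(params), X, y, config$n_layers,
                    config$n_qubits, k)
  } else {
    cpp_grad_fd(as.numeric(params), X, y, config$n_layers,
                config$n_qubits, k, h)
  }
  array(g, dim = dim(params))
}
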