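#' Save and load classifier checkpoints as JSON
#'
#' A checkpoint is a plain JSON document carrying the full configuration,
#' the trained angles as nested lists (layer, then qubit, then the three
#' `Rot` angles), the seed, and the per-epoch loss history. Angles are
#' serialized at full double precision so a save/load round trip reproduces
#' the fit bit-exactly.
#'
#' @param fit A `drc_fit` from [drc_train()].
#' @param path Output / input file path.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns a `drc_fit`.
#' @export
write_checkpoint <- function(fit, path) {
  if (!inherits(fit, "drc_fit")) stop("`fit` must be a drc_fit", call. = FALSE)
  L <- fit$ansatz$n_layers
  Q <- fit$ansatz$n_qubits
  angles <- lapply(seq_len(L), function(l) {
    lapply(seq_len(Q), function(q) as.numeric(fit$params[l, q, ]))
  })
  doc <- list(
    format = "reuploadr-checkpoint-v1",
    config = unclass(fit$config),
    seed = fit$config$seed,
    angles = angles,
    loss_history = as.numeric(fit$loss_history)
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "reuploadr-checkpoint-v1")) {
    stop("not a reuploadr checkpoint: ", path, call. = FALSE)
  }
  cfg <- doc$config
  config <- train_config(
    n_qubits = cfg$n_qubits, n_layers = cfg$n_layers,
    n_classes = cfg$n_classes, learning_rate = cfg$learning_rate,
    batch_size = cfg$batch_size, epochs = cfg$epochs, seed = cfg$seed,
    rho = cfg$rho, epsilon = cfg$epsilon, gradient = cfg$gradient
  )
  ansatz <- as_ansatz_config(config)
  L <- config$n_layers
  Q <- config$n_qubits
  if (length(doc$angles) != L ||
      any(vapply(doc$angles, length, 1L) != Q)) {
    stop("checkpoint angle shape does not match its config", call. = FALSE)
  }
  params <- array(0, dim = c(L, Q, 3L))
  for (l in seq_len(L)) {
    for (q in seq_len(Q)) {
      a <- as.numeric(unlist(doc$angles[[l]][[q]]))
      if (length(a) != 3L) {
        stop("checkpoint angle shape does not match its config",
             call. = FALSE)
      }
      params[l, q, ] <- a
    }
  }
  structure(
    list(params = params,
         loss_history = as.numeric(unlist(doc$loss_history)),
         config = config, ansatz = ansatz),
    class = "drc_fit"
  )
}
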