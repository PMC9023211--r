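# Independent oracles used across the suite.
#
# The Kronecker-product oracle builds the full 2^n x 2^n matrix of a gate
# embedded in the register (identities on every other qubit, qubit 0 the
# leftmost factor) and multiplies the raw amplitude vector. It shares no
# code with apply_1q()/apply_cnot(), which update amplitudes in place.

kron_embed_1q <- function(gate, qubit, n) {
  mats <- rep(list(diag(2) + 0i), n)
  mats[[qubit + 1L]] <- gate
  Reduce(`%x%`, mats)
}

cnot_full <- function(control, target, n) {
  dim <- 2^n
  m <- matrix(0 + 0i, dim, dim)
  for (i in 0:(dim - 1)) {
    cbit <- i %/% 2^(n - 1 - control) %% 2
    j <- if (cbit == 1) bitwXor(i, 2^(n - 1 - target)) else i
    m[j + 1, i + 1] <- 1
  }
  m
}

oracle_apply <- function(full_matrix, state) {
  amps <- as.complex(unclass(state))
  as.complex(full_matrix %*% amps)
}

# full-circuit oracle: one reuploading layer as an explicit matrix product
oracle_layer_matrix <- function(layer_angles, x, n) {
  full <- diag(2^n) + 0i
  for (q in seq_len(n) - 1L) {
    inj <- pi * x[q + 1L]
    g <- gate_rot(layer_angles[q + 1L, 1L] + inj,
                  layer_angles[q + 1L, 2L] + inj,
                  layer_angles[q + 1L, 3L] + inj)
    full <- kron_embed_1q(g, q, n) %*% full
  }
  for (q in seq_len(n - 1L) - 1L) {
    full <- cnot_full(q, q + 1L, n) %*% full
  }
  full
}

oracle_forward <- function(params, x, config) {
  n <- config$n_qubits
  amps <- complex(2^n)
  amps[1] <- 1
  x <- c(x, rep(0, n - length(x)))
  for (l in seq_len(config$n_layers)) {
    amps <- oracle_layer_matrix(matrix(params[l, , ], ncol = 3), x, n) %*% amps
    amps <- as.complex(amps)
  }
  p <- Mod(amps)^2
  k <- length(config$readout_qubits)
  idx <- 0:(2^n - 1)
  outcome <- integer(length(idx))
  for (j in seq_len(k)) {
    outcome <- outcome +
      (idx %/% 2^(n - 1 - config$readout_qubits[j]) %% 2) * 2^(k - j)
  }
  as.numeric(tapply(p, factor(outcome, levels = 0:(2^k - 1)), sum,
                    default = 0))
}

# per-class one-vs-rest accuracy recomputed sample-wise from the counts,
# independent of the matrix algebra in metrics_report()
ovr_accuracy_from_cm <- function(cm) {
  K <- nrow(cm)
  y_true <- rep(rep(seq_len(K) - 1L, K), times = as.integer(t(cm)))
  y_pred <- rep(rep(seq_len(K) - 1L, each = K), times = as.integer(t(cm)))
  vapply(seq_len(K) - 1L, function(cls) {
    mean((y_true == cls) == (y_pred == cls))
  }, numeric(1))
}

random_unitary_2x2 <- function() {
  # QR of a complex Ginibre draw, phase-fixed
  m <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q %*% diag(d / Mod(d))
}

basis_state <- function(n, index) {
  s <- zero_state(n)
  amp <- complex(2^n)
  amp[index + 1L] <- 1
  attributes(amp) <- attributes(s)
  amp
}

# global-phase-insensitive state comparison
expect_same_state <- function(a, b, tol = 1e-10) {
  overlap <- Mod(sum(Conj(unclass(a)) * unclass(b)))
  expect_lt(abs(overlap - 1), tol)
}
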