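#' n-qubit statevectors and exact gate application
#'
#' A statevector is the full complex amplitude vector of an `n`-qubit
#' register: length `2^n`, unit L2 norm. Qubit 0 is the *leftmost* tensor
#' factor, i.e. the most significant bit of the computational basis index,
#' so on two qubits the basis order is |00>, |01>, |10>, |11> and applying a
#' gate to qubit 0 of |00> touches the |00>/|10> pair.
#'
#' Simulation is exact (dense double-precision complex arithmetic): no shot
#' noise, no density matrices. Register sizes are capped at 12 qubits, the
#' point beyond which a dense `2^n` vector stops being the right tool.
#'
#' @name statevector
NULL

MAX_QUBITS <- 12L

new_statevector <- function(amplitudes, n_qubits) {
  structure(amplitudes, n_qubits = as.integer(n_qubits), class = "statevector")
}

#' @export
print.statevector <- function(x, ...) {
  n <- n_qubits(x)
  cat("<statevector: ", n, " qubit", if (n > 1) "s", ">\n", sep = "")
  labs <- basis_labels(n)
  amp <- unclass(x)
  show <- Mod(amp) > 1e-12
  if (!any(show)) show[1] <- TRUE
  for (i in which(show)) {
    cat(sprintf("  |%s>  %s\n", labs[i], format(amp[i], digits = 4)))
  }
  invisible(x)
}

#' Number of qubits of a statevector
#' @param state A statevector.
#' @return Integer number of qubits.
#' @export
n_qubits <- function(state) {
  attr(state, "n_qubits")
}

basis_labels <- function(n) {
  idx <- 0:(2^n - 1)
  vapply(idx, function(i) {
    paste(rev((i %/% 2^(0:(n - 1))) %% 2), collapse = "")
  }, character(1))
}

check_statevector <- function(state) {
  if (!inherits(state, "statevector")) {
    stop("`state` must be a statevector", call. = FALSE)
  }
  n <- n_qubits(state)
  if (length(state) != 2^n) {
    stop("statevector length does not match its qubit count", call. = FALSE)
  }
  invisible(state)
}

#' Prepare the all-zeros basis state |0...0>
#'
#' @param n_qubits Number of qubits, between 1 and 12.
#' @return A statevector with amplitude 1 on basis state 0.
#' @examples
#' zero_state(2)
#' @export
zero_state <- function(n_qubits) {
  if (!is.numeric(n_qubits) || length(n_qubits) != 1L || is.na(n_qubits) ||
      n_qubits != as.integer(n_qubits) || n_qubits < 1L || n_qubits > MAX_QUBITS) {
    stop("`n_qubits` must be an integer between 1 and ", MAX_QUBITS, call. = FALSE)
  }
  amp <- complex(2^n_qubits)
  amp[1] <- 1 + 0i
  new_statevector(amp, n_qubits)
}

#' Apply a single-qubit gate to one qubit of a register
#'
#' Transforms only the addressed qubit's tensor factor; all other amplitudes
#' mix only within pairs that differ in that qubit's bit.
#'
#' @param state A statevector.
#' @param gate A unitary 2x2 complex matrix (see [gates]).
#' @param qubit Zero-based qubit index; qubit 0 is the most significant bit
#'   of the basis index.
#' @return The transformed statevector (unit norm).
#' @examples
#' apply_1q(zero_state(2), gate_hadamard(), 0)
#' @export
apply_1q <- function(state, gate, qubit) {
  check_statevector(state)
  n <- n_qubits(state)
  if (!is.numeric(qubit) || length(qubit) != 1L || is.na(qubit) ||
      qubit < 0 || qubit >= n || qubit != as.integer(qubit)) {
    stop("`qubit` must be an index in [0, ", n, ")", call. = FALSE)
  }
  if (!is.matrix(gate) || !all(dim(gate) == c(2L, 2L))) {
    stop("`gate` must be a 2x2 matrix", call. = FALSE)
  }
  if (!is_unitary(gate)) {
    stop("`gate` must be unitary", call. = FALSE)
  }
  amp <- as.complex(unclass(state))
  # indices (0-based) whose addressed bit is 0, paired with index + stride
  stride <- 2^(n - 1 - qubit)
  idx <- 0:(2^n - 1)
  lo <- idx[idx %/% stride %% 2 == 0]
  hi <- lo + stride
  a0 <- amp[lo + 1]
  a1 <- amp[hi + 1]
  amp[lo + 1] <- gate[1, 1] * a0 + gate[1, 2] * a1
  amp[hi + 1] <- gate[2, 1] * a0 + gate[2, 2] * a1
  new_statevector(amp, n)
}

#' Apply a CNOT gate
#'
#' Flips the target qubit on every basis state whose control qubit is 1;
#' basis states with control 0 are untouched.
#'
#' @param state A statevector.
#' @param control,target Distinct zero-based qubit indices.
#' @return The transformed statevector.
#' @examples
#' # Bell state: H on qubit 0, then CNOT(0, 1)
#' apply_cnot(apply_1q(zero_state(2), gate_hadamard(), 0), 0, 1)
#' @export
apply_cnot <- function(state, control, target) {
  check_statevector(state)
  n <- n_qubits(state)
  for (q in c(control, target)) {
    if (!is.numeric(q) || length(q) != 1L || is.na(q) ||
        q < 0 || q >= n || q != as.integer(q)) {
      stop("control and target must be indices in [0, ", n, ")", call. = FALSE)
    }
  }
  if (control == target) {
    stop("`control` and `target` must differ", call. = FALSE)
  }
  amp <- as.complex(unclass(state))
  idx <- 0:(2^n - 1)
  cstride <- 2^(n - 1 - control)
  tstride <- 2^(n - 1 - target)
  # control bit 1 and target bit 0: swap with the target-flipped partner
  sel <- idx %/% cstride %% 2 == 1 & idx %/% tstride %% 2 == 0
  a <- idx[sel]
  b <- a + tstride
  tmp <- amp[a + 1]
  amp[a + 1] <- amp[b + 1]
  amp[b + 1] <- tmp
  new_statevector(amp, n)
}

#' Born-rule outcome probabilities
#'
#' `measure_probs()` returns the squared-magnitude probability of every
#' computational basis state. `marginal_probs()` returns the marginal
#' distribution of a subset of qubits, summing the Born probabilities over
#' every qubit not listed; the first listed qubit is the most significant
#' bit of the outcome index.
#'
#' @param state A statevector.
#' @param qubits Distinct zero-based qubit indices to keep.
#' @return A numeric probability vector (length `2^n` or `2^length(qubits)`)
#'   summing to 1.
#' @examples
#' bell <- apply_cnot(apply_1q(zero_state(2), gate_hadamard(), 0), 0, 1)
#' measure_probs(bell)        # 0.5 on |00> and |11>
#' marginal_probs(bell, 0)    # (0.5, 0.5)
#' @export
measure_probs <- function(state) {
  check_statevector(state)
  as.numeric(Mod(unclass(state))^2)
}

#' @rdname measure_probs
#' @export
marginal_probs <- function(state, qubits) {
  check_statevector(state)
  n <- n_qubits(state)
  qubits <- as.integer(qubits)
  if (length(qubits) == 0L || anyNA(qubits) || any(qubits < 0L | qubits >= n) ||
      anyDuplicated(qubits) > 0L) {
    stop("`qubits` must be distinct indices in [0, ", n, ")", call. = FALSE)
  }
  p <- measure_probs(state)
  idx <- 0:(2^n - 1)
  k <- length(qubits)
  outcome <- integer(length(idx))
  for (j in seq_len(k)) {
    bit <- idx %/% 2^(n - 1 - qubits[j]) %% 2
    outcome <- outcome + bit * 2^(k - j)
  }
  as.numeric(tapply(p, factor(outcome, levels = 0:(2^k - 1)), sum, default = 0))
}
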