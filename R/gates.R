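#' Single- and two-qubit gate matrices
#'
#' Constructors for the unitary gate matrices used by the classifier circuit:
#' the Hadamard gate, the parametric axis rotations `RX`, `RY`, `RZ`, and the
#' general single-qubit rotation `Rot(phi, theta, omega)` which rotates about
#' the z-axis, then the y-axis, then the z-axis again.
#'
#' All matrices are 2x2 complex and unitary to better than 1e-10. Angles are
#' in radians. `gate_rot()` is the composition `RZ(omega) %*% RY(theta) %*%
#' RZ(phi)` (rightmost factor acts first), so `gate_rot(0, theta, 0)` equals
#' `gate_ry(theta)`.
#'
#' @param phi,theta,omega Rotation angles in radians; must be finite.
#' @return A 2x2 complex matrix.
#' @examples
#' gate_hadamard() %*% c(1, 0)          # equal superposition of |0> and |1>
#' all.equal(gate_rot(0, pi / 3, 0), gate_ry(pi / 3))
#' @name gates
NULL

check_angle <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

#' @rdname gates
#' @export
gate_hadamard <- function() {
  matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE) / sqrt(2) + 0i
}

#' @rdname gates
#' @export
gate_rx <- function(phi) {
  check_angle(phi, "phi")
  c <- cos(phi / 2)
  s <- sin(phi / 2)
  matrix(c(c + 0i, -1i * s, -1i * s, c + 0i), 2, 2, byrow = TRUE)
}

#' @rdname gates
#' @export
gate_ry <- function(phi) {
  check_angle(phi, "phi")
  c <- cos(phi / 2)
  s <- sin(phi / 2)
  matrix(c(c, -s, s, c) + 0i, 2, 2, byrow = TRUE)
}

#' @rdname gates
#' @export
gate_rz <- function(phi) {
  check_angle(phi, "phi")
  diag(c(exp(-1i * phi / 2), exp(1i * phi / 2)))
}

#' @rdname gates
#' @export
gate_rot <- function(phi, theta, omega) {
  check_angle(phi, "phi")
  check_angle(theta, "theta")
  check_angle(omega, "omega")
  gate_rz(omega) %*% gate_ry(theta) %*% gate_rz(phi)
}

#' Test a matrix for unitarity
#'
#' @param gate A square complex matrix.
#' @param tol Maximum allowed entrywise deviation of `G^dagger G` from the
#'   identity. Default 1e-10.
#' @return `TRUE` or `FALSE`.
#' @export
is_unitary <- function(gate, tol = 1e-10) {
  if (!is.matrix(gate) || nrow(gate) != ncol(gate)) return(FALSE)
  delta <- Conj(t(gate)) %*% gate - diag(nrow(gate))
  max(Mod(delta)) < tol
}
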