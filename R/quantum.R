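#' Quantum walk Hamiltonian on the evidence lattice
#'
#' Builds the tridiagonal Hermitian Hamiltonian of a continuous-time quantum
#' walk: diagonal entries hold the potential `mu(x) = a + b x + c x^2`
#' evaluated at the level values `x_j = j / (n - 1)` (the likelihood scale),
#' and the sub-/super-diagonals hold the coupling `sigma` that spreads
#' amplitude between neighbouring levels. A linearly increasing potential
#' (`b > 0, a = c = 0`) tilts the squared-amplitude distribution towards high
#' evidence; reflection at the lattice bounds then produces the oscillation
#' and interference characteristic of the quantum walk.
#'
#' @param n Number of levels (>= 2).
#' @param a,b,c Quadratic-potential coefficients (dimensionless).
#' @param sigma Nearest-neighbour coupling.
#' @return An object of class `hamiltonian` with fields `matrix`, `n`,
#'   `potential` (the coefficients), and `sigma`.
#' @examples
#' hamiltonian_walk(2, sigma = 1)$matrix   # [[0, 1], [1, 0]]
#' @export
hamiltonian_walk <- function(n, a = 0, b = 0, c = 0, sigma = 1) {
  n <- as.integer(n)
  if (n < 2L) abort("`n` must be >= 2.")
  x <- seq(0, 1, length.out = n)
  H <- matrix(0, n, n)
  diag(H) <- a + b * x + c * x^2
  for (j in seq_len(n - 1)) {
    H[j, j + 1] <- sigma
    H[j + 1, j] <- sigma
  }
  structure(
    list(matrix = H, n = n, potential = c(a = a, b = b, c = c), sigma = sigma),
    class = "hamiltonian"
  )
}

#' @export
print.hamiltonian <- function(x, ...) {
  cat("<hamiltonian> n = ", x$n, ", potential (a,b,c) = (",
      paste(x$potential, collapse = ", "), "), sigma = ", x$sigma, "\n",
      sep = "")
  invisible(x)
}

# Hermitian eigendecomposition, reused for all propagators of one H.
ham_eigen <- function(H) {
  stopifnot(inherits(H, "hamiltonian"))
  if (is.null(H$eigen)) eigen(H$matrix, symmetric = TRUE) else H$eigen
}

#' Unitary propagator of a quantum walk
#'
#' `U(t) = exp(-i H t)`, computed through the Hermitian eigendecomposition of
#' `H` (numerically stable and exactly unitary up to rounding).
#'
#' @param H A [hamiltonian_walk()].
#' @param t Real time.
#' @return Complex `n x n` unitary matrix.
#' @export
unitary <- function(H, t) {
  e <- ham_eigen(H)
  V <- e$vectors + 0i
  V %*% (exp(-1i * e$values * t) * Conj(t(V)))
}

#' Propagate an amplitude state unitarily
#'
#' `psi(t) = exp(-i H t) psi(0)`; the L2 norm is preserved.
#'
#' @param H A [hamiltonian_walk()].
#' @param psi0 Initial `amplitude_state`.
#' @param t Real time.
#' @return An `amplitude_state`.
#' @export
propagate_amplitude <- function(H, psi0, t) {
  stopifnot(inherits(psi0, "amplitude_state"))
  if (length(psi0) != H$n) abort("state/Hamiltonian dimension mismatch")
  amplitude_state(as.vector(unitary(H, t) %*% unclass(psi0)))
}

#' Propagate a density state unitarily
#'
#' `rho(t) = U(t) rho(0) U(t)^dagger`; trace, Hermiticity and the full
#' eigenvalue spectrum are preserved.
#'
#' @param H A [hamiltonian_walk()].
#' @param rho0 Initial `density_state`.
#' @param t Real time.
#' @return A `density_state`.
#' @export
propagate_unitary <- function(H, rho0, t) {
  stopifnot(inherits(rho0, "density_state"))
  if (nrow(rho0) != H$n) abort("state/Hamiltonian dimension mismatch")
  U <- unitary(H, t)
  density_state(U %*% unclass(rho0) %*% Conj(t(U)),
                allow_nonpositive = attr(rho0, "min_eigenvalue") < -ow_tol("psd"))
}

#' Projective collapse of a density state (Lueders rule)
#'
#' Applies the projector sandwich `M rho M^dagger`. The trace of the
#' unnormalised post-state is the outcome probability; the conditional
#' post-measurement state renormalises by it.
#'
#' @param M A [projector()].
#' @param rho A `density_state`.
#' @param renormalize Return the conditional (trace-one) post-state
#'   (default) or the unnormalised sandwich.
#' @return List with `probability` and `state` (a `density_state` when
#'   renormalised, a plain complex matrix otherwise).
#' @export
collapse <- function(M, rho, renormalize = TRUE) {
  stopifnot(inherits(M, "response_projector"), inherits(rho, "density_state"))
  if (M$n_levels != nrow(rho)) abort("projector/state dimension mismatch")
  post <- project_sandwich(M, unclass(rho))
  p <- Re(sum(diag(post)))
  if (!renormalize) return(list(probability = p, state = post))
  if (p <= ow_tol("trace"))
    abort("zero-probability outcome: conditional state undefined")
  list(probability = p, state = density_state(post / p))
}

# M rho M^dagger for a diagonal 0/1 projector: zero out non-selected rows and
# columns (O(N^2), no matrix products needed).
project_sandwich <- function(M, rho) {
  keep <- diag(M$matrix) != 0
  out <- matrix(0i, nrow(rho), ncol(rho))
  out[keep, keep] <- rho[keep, keep]
  out
}

#' Joint probability of timed sequential quantum measurements
#'
#' Alternates unitary propagation and unnormalised Lueders projection along
#' the schedule. For an amplitude initial state the result is the squared
#' norm of `M_k U(dt_k) ... M_1 U(t_1) psi(0)`; for a density it is the trace
#' of the corresponding projector-sandwich chain. The two forms agree for
#' pure initial states. Because the intermediate projection changes the
#' state, marginalising over an intermediate measurement need not reproduce
#' the unmeasured marginal — the interference effect quantified by
#' [interference_statistic()].
#'
#' @param H A [hamiltonian_walk()].
#' @param state0 Initial `amplitude_state` or `density_state`.
#' @param projectors List of [projector()]s.
#' @param times Strictly increasing positive measurement times.
#' @return The joint probability.
#' @export
joint_response_probability_quantum <- function(H, state0, projectors, times) {
  check_schedule(projectors, times, H$n)
  if (inherits(state0, "amplitude_state")) {
    v <- as.complex(unclass(state0))
    t_prev <- 0
    for (s in seq_along(times)) {
      v <- as.vector(unitary(H, times[s] - t_prev) %*% v)
      v <- diag(projectors[[s]]$matrix) * v
      t_prev <- times[s]
    }
    return(sum(Mod(v)^2))
  }
  stopifnot(inherits(state0, "density_state"))
  rho <- unclass(state0)
  t_prev <- 0
  for (s in seq_along(times)) {
    U <- unitary(H, times[s] - t_prev)
    rho <- U %*% rho %*% Conj(t(U))
    rho <- project_sandwich(projectors[[s]], rho)
    t_prev <- times[s]
  }
  Re(sum(diag(rho)))
}
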