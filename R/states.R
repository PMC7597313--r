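#' State representations on the evidence lattice
#'
#' Three representations are used. A *probability state* is a real vector
#' `p` with non-negative entries summing to one (the classical, L1-normalised
#' representation). An *amplitude state* is a complex vector `a` whose squared
#' magnitudes sum to one (the quantum, L2-normalised representation). A
#' *density state* is a complex Hermitian trace-one matrix `rho`; its diagonal
#' holds the observable level probabilities and its off-diagonals the
#' coherences. Densities are validated as positive semidefinite unless
#' `allow_nonpositive = TRUE`, which marks the state non-physical while
#' keeping trace and Hermiticity checks (useful when a non-PSD Lindblad
#' coupling drives the dynamics outside the density cone).
#'
#' @param p,a Numeric (resp. complex) vector of per-level values.
#' @param m Complex square matrix.
#' @param allow_nonpositive Accept densities with negative eigenvalues.
#' @return A classed vector (`probability_state`, `amplitude_state`) or matrix
#'   (`density_state`). `density_state` carries a `min_eigenvalue` attribute.
#' @name states
NULL

#' @rdname states
#' @export
probability_state <- function(p) {
  p <- as.numeric(p)
  if (any(p < -ow_tol("l1_norm"))) abort("probabilities must be non-negative")
  if (abs(sum(p) - 1) > ow_tol("l1_norm") * max(1, length(p)))
    abort(sprintf("probabilities must sum to 1 (got %.15g)", sum(p)))
  structure(pmax(p, 0), class = "probability_state")
}

#' @rdname states
#' @export
amplitude_state <- function(a) {
  a <- as.complex(a)
  nrm <- sum(Mod(a)^2)
  if (abs(nrm - 1) > ow_tol("l2_norm") * max(1, length(a)))
    abort(sprintf("squared amplitude magnitudes must sum to 1 (got %.15g)", nrm))
  structure(a, class = "amplitude_state")
}

#' @rdname states
#' @export
density_state <- function(m, allow_nonpositive = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("density must be square")
  if (!is.complex(m)) m <- m + 0i
  if (max(Mod(m - Conj(t(m)))) > ow_tol("hermitian"))
    abort("density must be Hermitian")
  tr <- Re(sum(diag(m)))
  if (abs(tr - 1) > ow_tol("trace"))
    abort(sprintf("density trace must be 1 (got %.12g)", tr))
  m <- (m + Conj(t(m))) / 2
  lam_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (!allow_nonpositive && lam_min < -ow_tol("psd"))
    abort(sprintf("density has negative eigenvalue %.3e; pass allow_nonpositive = TRUE to keep a non-physical state", lam_min))
  structure(m, class = "density_state", min_eigenvalue = lam_min)
}

#' @export
print.probability_state <- function(x, ...) {
  cat("<probability_state> n =", length(x), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.amplitude_state <- function(x, ...) {
  cat("<amplitude_state> n =", length(x), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.density_state <- function(x, ...) {
  cat("<density_state> ", nrow(x), "x", ncol(x),
      "  min eigenvalue ", format(attr(x, "min_eigenvalue"), digits = 3),
      "\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6) cat("... (truncated)\n")
  invisible(x)
}

#' Truncated-Gaussian initial probability state
#'
#' A discrete approximation to a Gaussian over the lattice: entries are
#' proportional to `exp(-(j - center)^2 / (2 sd^2))`, truncated to the lattice
#' (no wrap-around) and renormalised. The spread defaults to a tenth of the
#' lattice width.
#'
#' @param scale An [evidence_scale()].
#' @param center Centre level index (0-based), defaults to the middle level.
#' @param sd Standard deviation in level units, positive.
#' @return A `probability_state`.
#' @export
gaussian_probability <- function(scale, center = (scale$n_levels - 1) / 2,
                                 sd = scale$n_levels / 10) {
  stopifnot(inherits(scale, "evidence_scale"))
  if (!is.numeric(sd) || sd <= 0) abort("`sd` must be positive.")
  n <- scale$n_levels
  if (center < 0 || center > n - 1) abort("`center` must lie in 0..n_levels-1.")
  j <- 0:(n - 1)
  logw <- -(j - center)^2 / (2 * sd^2)
  w <- exp(logw - max(logw))   # guard underflow in the near-delta limit
  probability_state(w / sum(w))
}

#' Convert a probability state to an amplitude state
#'
#' Takes entrywise square roots, giving the real non-negative wave function
#' whose squared magnitudes reproduce the probabilities.
#'
#' @param p A `probability_state`.
#' @return An `amplitude_state`.
#' @export
probability_to_amplitude <- function(p) {
  stopifnot(inherits(p, "probability_state"))
  amplitude_state(sqrt(unclass(p)))
}

#' Pure density from an amplitude state
#'
#' Forms the rank-one projector `rho = psi psi^dagger`.
#'
#' @param psi An `amplitude_state`.
#' @return A `density_state`.
#' @export
pure_density <- function(psi) {
  stopifnot(inherits(psi, "amplitude_state"))
  v <- as.complex(unclass(psi))
  density_state(v %*% t(Conj(v)))
}

#' Mixture density from pure states
#'
#' Probability mixture `rho = sum_j p_j psi_j psi_j^dagger` across pure states.
#'
#' @param weights Non-negative weights summing to one.
#' @param states List of `amplitude_state`s of equal dimension.
#' @return A `density_state`.
#' @export
mixture_density <- function(weights, states) {
  if (length(weights) != length(states))
    abort("`weights` and `states` must have equal length.")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    abort("`weights` must be a probability simplex vector.")
  dims <- vapply(states, length, integer(1))
  if (length(unique(dims)) != 1L) abort("all states must share one dimension.")
  n <- dims[1]
  rho <- matrix(0i, n, n)
  for (j in seq_along(states)) {
    v <- as.complex(unclass(states[[j]]))
    rho <- rho + weights[j] * (v %*% t(Conj(v)))
  }
  density_state(rho)
}

#' Mean evidence of a state
#'
#' The expectation of the level value (likelihood, in `[0, 1]`) under the
#' state's level probabilities: `sum_j (j / (N - 1)) p_j`, with `p` the
#' probability vector or the density diagonal.
#'
#' @param state A `probability_state` or `density_state`.
#' @param scale The matching [evidence_scale()].
#' @return A number in `[0, 1]`.
#' @export
mean_evidence <- function(state, scale) {
  stopifnot(inherits(scale, "evidence_scale"))
  p <- level_probabilities(state)
  if (length(p) != scale$n_levels) abort("state/scale dimension mismatch")
  sum(scale$values * p)
}

#' Observable level probabilities of any state representation
#'
#' @param state A `probability_state`, `amplitude_state`, or `density_state`.
#' @return Numeric vector of per-level probabilities.
#' @export
level_probabilities <- function(state) {
  if (inherits(state, "probability_state")) return(as.numeric(unclass(state)))
  if (inherits(state, "amplitude_state")) return(Mod(unclass(state))^2)
  if (inherits(state, "density_state")) return(Re(diag(unclass(state))))
  abort("unsupported state type")
}

#' @export
as_tibble.probability_state <- function(x, ...) {
  tibble::tibble(level = seq_along(x) - 1L, probability = as.numeric(unclass(x)))
}

#' @export
as_tibble.amplitude_state <- function(x, ...) {
  a <- unclass(x)
  tibble::tibble(level = seq_along(a) - 1L,
                 re = Re(a), im = Im(a), probability = Mod(a)^2)
}
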