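#' Lindblad coupling matrices
#'
#' The dissipator of the master equation weights the elementary transition
#' operators `L_ij = |i><j|` by coefficients `gamma_ij` collected in a matrix
#' `G`. Three choices connect `G` to a Markov walk with generator `K`:
#'
#' * `lindblad_from_generator()`: `G = K`. Columns sum to zero, so the
#'   coherences do not decay, and at full dissipator weight the density
#'   diagonal follows the Markov walk exactly. `K` is not positive
#'   semidefinite, so positivity of the density is no longer guaranteed.
#' * `lindblad_from_transition()`: `G = T(tau) = exp(K tau)`. Columns sum to
#'   one, so at full weight every coherence decays as `exp(-t)` and the
#'   diagonal follows the slowed flow `d phi/dt = (T(tau) - I) phi`. `G` is a
#'   PSD-diagnosable stochastic matrix, keeping the density physical.
#' * `lindblad_from_scaled_transition()`: `G = T(tau)/tau` with small `tau`.
#'   The diagonal flow `(T(tau) - I)/tau` approximates `K` while coherences
#'   decay at the fast rate `1/tau`.
#'
#' Positive semidefiniteness of `G` is diagnosed (eigenvalue check) and
#' recorded in the `psd` field — never enforced, so the non-PSD `G = K`
#' choice remains available for study.
#'
#' @param K A [markov_generator()].
#' @param tau Time-scale parameter (positive; for the scaled variant in
#'   `(0, 1]`).
#' @return An object of class `lindblad_coupling` with fields `gamma`,
#'   `kind`, `tau`, `psd`, and `column_sums`.
#' @name lindblad_coupling
NULL

new_coupling <- function(gamma, kind, tau = NA_real_) {
  ev <- eigen((gamma + t(gamma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(gamma = gamma, kind = kind, tau = tau,
         psd = min(ev) >= -1e-10, column_sums = colSums(gamma)),
    class = "lindblad_coupling"
  )
}

#' @rdname lindblad_coupling
#' @export
lindblad_from_generator <- function(K) {
  stopifnot(inherits(K, "markov_generator"))
  new_coupling(K$matrix, "generator")
}

#' @rdname lindblad_coupling
#' @export
lindblad_from_transition <- function(K, tau = 1) {
  stopifnot(inherits(K, "markov_generator"))
  if (tau <= 0) abort("`tau` must be positive.")
  new_coupling(transition_matrix(K, tau)$matrix, "transition", tau)
}

#' @rdname lindblad_coupling
#' @export
lindblad_from_scaled_transition <- function(K, tau) {
  stopifnot(inherits(K, "markov_generator"))
  if (tau <= 0 || tau > 1) abort("`tau` must lie in (0, 1].")
  new_coupling(transition_matrix(K, tau)$matrix / tau, "scaled_transition", tau)
}

#' Custom Lindblad coupling
#'
#' Wraps an arbitrary real coefficient matrix as a coupling; its PSD status
#' and column sums are diagnosed as for the built-in kinds.
#'
#' @param gamma Real square matrix of coefficients.
#' @export
lindblad_coupling <- function(gamma) {
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != ncol(gamma) || !is.numeric(gamma))
    abort("`gamma` must be a real square matrix.")
  new_coupling(gamma, "custom")
}

#' @export
print.lindblad_coupling <- function(x, ...) {
  cat("<lindblad_coupling> kind = ", x$kind,
      if (!is.na(x$tau)) paste0(" (tau = ", x$tau, ")"),
      ", n = ", nrow(x$gamma), ", PSD: ", x$psd, "\n", sep = "")
  invisible(x)
}

#' Coherence decay rates implied by a coupling
#'
#' At full dissipator weight each off-diagonal density entry `rho_kl`
#' (`k != l`) obeys `d rho_kl / dt = -0.5 (c_k + c_l) rho_kl` with
#' `c_k = sum_i gamma_ik` the column sums of `G`; for the built-in kinds the
#' columns are constant, giving rate 0 (`G = K`), 1 (`G = T(tau)`), or
#' `1/tau` (`G = T(tau)/tau`).
#'
#' @param G A `lindblad_coupling`.
#' @return Numeric vector of per-column rates `c_k`.
#' @export
coherence_decay_rates <- function(G) {
  stopifnot(inherits(G, "lindblad_coupling"))
  G$column_sums
}
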