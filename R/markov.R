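#' Continuous-time Markov random walk on the evidence lattice
#'
#' `markov_generator()` builds the tridiagonal intensity matrix `K` of a
#' birth-death walk with reflecting bounds: rate `beta` for a step up (towards
#' higher evidence), rate `alpha` for a step down. Interior diagonal entries
#' are `-(alpha + beta)`; the reflecting corners carry `-beta` (bottom) and
#' `-alpha` (top) so that every column sums to zero. The walk's mean drift is
#' `mu = (beta - alpha) / 2` and its diffusion rate `sigma2 = (beta + alpha) / 2`;
#' positive drift pushes probability towards higher evidence levels.
#'
#' @param n Number of levels (>= 2).
#' @param alpha Downward transition rate (events per unit time), >= 0.
#' @param beta Upward transition rate, >= 0; `alpha + beta > 0`.
#' @return An object of class `markov_generator` with fields `matrix`, `n`,
#'   `alpha`, `beta`, `drift`, `diffusion`.
#' @examples
#' K <- markov_generator(2, alpha = 1, beta = 2)
#' K$matrix       # [[-2, 1], [2, -1]]
#' K$drift        # 0.5
#' @export
markov_generator <- function(n, alpha, beta) {
  n <- as.integer(n)
  if (n < 2L) abort("`n` must be >= 2.")
  if (alpha < 0 || beta < 0) abort("rates must be non-negative.")
  if (alpha + beta <= 0) abort("at least one rate must be positive.")
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (j < n) K[j + 1, j] <- beta   # up-move from level j-1
    if (j > 1) K[j - 1, j] <- alpha  # down-move
  }
  diag(K) <- -colSums(K)
  structure(
    list(matrix = K, n = n, alpha = alpha, beta = beta,
         drift = (beta - alpha) / 2, diffusion = (beta + alpha) / 2),
    class = "markov_generator"
  )
}

#' @export
print.markov_generator <- function(x, ...) {
  cat("<markov_generator> n = ", x$n, ", alpha = ", x$alpha, ", beta = ",
      x$beta, " (drift ", x$drift, ")\n", sep = "")
  invisible(x)
}

#' Transition matrix of a Markov walk
#'
#' Computes `T(t) = exp(K t)`. Columns sum to one and entries are
#' probabilities; the family satisfies the semigroup property
#' `T(s) T(t) = T(s + t)`.
#'
#' @param K A [markov_generator()].
#' @param t Non-negative time horizon.
#' @return An object of class `transition_matrix` with fields `matrix` and
#'   `horizon`.
#' @export
transition_matrix <- function(K, t) {
  stopifnot(inherits(K, "markov_generator"))
  if (t < 0) abort("`t` must be non-negative.")
  Tm <- as.matrix(Matrix::expm(K$matrix * t))
  cs <- colSums(Tm)
  if (max(abs(cs - 1)) > ow_tol("column"))
    ow_numerical_error("transition matrix columns drifted from 1")
  if (min(Tm) < -ow_tol("column"))
    ow_numerical_error("transition matrix has a negative entry")
  Tm[Tm < 0] <- 0
  structure(list(matrix = Tm, horizon = t), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> n = ", nrow(x$matrix), ", horizon t = ",
      x$horizon, "\n", sep = "")
  invisible(x)
}

#' Propagate a probability state under the Markov walk
#'
#' `phi(t) = exp(K t) phi(0)`.
#'
#' @param K A [markov_generator()].
#' @param phi0 Initial `probability_state`.
#' @param t Non-negative time.
#' @return A `probability_state`.
#' @export
propagate_markov <- function(K, phi0, t) {
  stopifnot(inherits(K, "markov_generator"), inherits(phi0, "probability_state"))
  if (length(phi0) != K$n) abort("state/generator dimension mismatch")
  Tm <- transition_matrix(K, t)
  probability_state(as.numeric(Tm$matrix %*% unclass(phi0)))
}

#' Response probability of a projective measurement
#'
#' For a probability state the L1 rule (sum of probabilities over the
#' projector's levels); for an amplitude state the L2 rule (squared norm of
#' the projected amplitudes); for a density the trace rule
#' `Tr(M rho M^dagger)`.
#'
#' @param M A [projector()].
#' @param state A `probability_state`, `amplitude_state`, or `density_state`.
#' @return Probability in `[0, 1]`.
#' @export
response_probability <- function(M, state) {
  stopifnot(inherits(M, "response_projector"))
  p <- level_probabilities(state)
  if (length(p) != M$n_levels) abort("state/projector dimension mismatch")
  sum(p[M$levels + 1L])
}

#' Joint probability of a sequence of timed Markov measurements
#'
#' Alternates propagation `T(dt)` and projection (zeroing the non-selected
#' levels without renormalisation) along the schedule, returning the L1 mass
#' of the final vector — the joint probability of observing every scheduled
#' response. With `conditional = TRUE` the renormalised post-sequence
#' distribution is also returned.
#'
#' @param K A [markov_generator()].
#' @param phi0 Initial `probability_state` at time 0.
#' @param projectors List of [projector()]s.
#' @param times Strictly increasing positive measurement times, one per
#'   projector.
#' @param conditional Also return the conditional distribution given all
#'   scheduled outcomes.
#' @return The joint probability, or (if `conditional`) a list with
#'   `probability` and `state`.
#' @export
joint_response_probability <- function(K, phi0, projectors, times,
                                       conditional = FALSE) {
  stopifnot(inherits(K, "markov_generator"), inherits(phi0, "probability_state"))
  check_schedule(projectors, times, K$n)
  v <- as.numeric(unclass(phi0))
  t_prev <- 0
  for (s in seq_along(times)) {
    Tm <- transition_matrix(K, times[s] - t_prev)
    v <- as.numeric(Tm$matrix %*% v)
    v <- diag(projectors[[s]]$matrix) * v
    t_prev <- times[s]
  }
  p <- sum(v)
  if (!conditional) return(p)
  if (p <= 0) abort("zero-probability outcome: conditional state undefined")
  list(probability = p, state = probability_state(v / p))
}

#' Invariant distribution of a Markov walk
#'
#' Solves `K phi = 0` for the unique stationary distribution of an
#' irreducible generator (the tridiagonal reflecting-bound walk with positive
#' rates qualifies; its stationary law is the detailed-balance geometric
#' profile `phi_j` proportional to `(beta/alpha)^j`).
#'
#' @param K A [markov_generator()].
#' @return A `probability_state`.
#' @export
invariant_distribution <- function(K) {
  stopifnot(inherits(K, "markov_generator"))
  sv <- svd(K$matrix)
  null_dim <- sum(sv$d < ow_tol("nullspace") * max(sv$d))
  if (null_dim != 1L)
    abort(sprintf("generator null space has dimension %d, not 1", null_dim))
  v <- sv$v[, K$n]
  v <- v / sum(v)
  if (min(v) < -1e-10) abort("stationary vector is not a distribution")
  probability_state(pmax(v, 0) / sum(pmax(v, 0)))
}

check_schedule <- function(projectors, times, n) {
  if (!is.list(projectors) || !all(vapply(projectors, inherits, logical(1),
                                          "response_projector")))
    abort("`projectors` must be a list of response projectors")
  if (length(projectors) != length(times))
    abort("`projectors` and `times` must have equal length")
  if (length(times) == 0L) abort("schedule must contain at least one measurement")
  if (any(diff(c(0, times)) <= 0))
    abort("`times` must be strictly increasing and positive")
  if (any(vapply(projectors, function(m) m$n_levels, integer(1)) != n))
    abort("projector dimension mismatch")
  invisible(TRUE)
}
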