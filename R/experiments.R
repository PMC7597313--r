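#' Choice-then-confidence paradigm design
#'
#' Describes the two-stage measurement paradigm: a first (choice)
#' measurement at `t1` and a final (confidence) measurement at `t2 > t1`.
#' Both measurement stages are complete projector partitions — their
#' projectors sum to the identity — so every trial yields exactly one
#' outcome per stage. In the companion *confidence-alone* condition the
#' first measurement is omitted (a pre-planned response that reads nothing
#' out), which for a Markov walk leaves the confidence distribution
#' unchanged and for a quantum walk does not.
#'
#' @param t1,t2 Measurement times, `0 < t1 < t2`.
#' @param choice List of [projector()]s partitioning the lattice (the
#'   choice alternatives).
#' @param confidence List of [projector()]s partitioning the lattice (the
#'   confidence ratings, e.g. [confidence_bins()]).
#' @return An object of class `paradigm_design`.
#' @export
paradigm_design <- function(t1, t2, choice, confidence) {
  if (!(t1 > 0 && t2 > t1)) abort("need 0 < t1 < t2.")
  check_partition(choice, "choice")
  check_partition(confidence, "confidence")
  if (choice[[1]]$n_levels != confidence[[1]]$n_levels)
    abort("choice and confidence projectors must share one lattice.")
  structure(list(t1 = t1, t2 = t2, choice = choice, confidence = confidence,
                 n = choice[[1]]$n_levels),
            class = "paradigm_design")
}

check_partition <- function(projs, what) {
  if (!is.list(projs) || length(projs) < 1L ||
      !all(vapply(projs, inherits, logical(1), "response_projector")))
    abort(sprintf("`%s` must be a list of response projectors.", what))
  n <- projs[[1]]$n_levels
  tot <- Reduce(`+`, lapply(projs, function(m) diag(m$matrix)))
  if (any(tot != 1))
    abort(sprintf("`%s` projectors must partition the lattice (sum to identity).", what))
  invisible(TRUE)
}

#' @export
print.paradigm_design <- function(x, ...) {
  cat("<paradigm_design> t1 = ", x$t1, ", t2 = ", x$t2, "; ",
      length(x$choice), " choice x ", length(x$confidence),
      " confidence outcomes on ", x$n, " levels\n", sep = "")
  invisible(x)
}

#' Two-level open-system trajectory
#'
#' The minimal worked example: two responses (up = level 0, down = level 1),
#' the linear-potential Hamiltonian `[[0, 1], [1, 1]]` (slope `b = 1`,
#' coupling `sigma = 1` on the two-level lattice), Markov rates `alpha`
#' (towards up) and `beta` (towards down). Tracks the probability of the
#' down state over the
#' grid for the open system with the requested coupling and weight. At
#' `w = 1` with `G = K` the trajectory is the pure Markov relaxation to
#' `beta / (alpha + beta)`; at intermediate `w` it oscillates first and then
#' settles to the coupling-dependent equilibrium.
#'
#' @param alpha,beta Markov rates.
#' @param w Mixing weight.
#' @param coupling One of `"generator"`, `"transition"`,
#'   `"scaled_transition"`.
#' @param tau Coupling time scale (for the transition kinds).
#' @param times Increasing time grid.
#' @param rho0 Initial `density_state` (default: pure up state).
#' @return A tibble (class `walk_trajectory`) with columns `time`, `p_down`,
#'   `p_up`, `coherence_l1`, `min_eigenvalue`.
#' @export
two_state_trajectory <- function(alpha, beta, w,
                                 coupling = c("generator", "transition",
                                              "scaled_transition"),
                                 tau = 1, times = seq(0, 20, by = 0.1),
                                 rho0 = NULL) {
  coupling <- match.arg(coupling)
  K <- markov_generator(2, alpha, beta)
  G <- switch(coupling,
              generator = lindblad_from_generator(K),
              transition = lindblad_from_transition(K, tau),
              scaled_transition = lindblad_from_scaled_transition(K, tau))
  model <- open_system(hamiltonian_walk(2, b = 1, sigma = 1), G, w)
  rho0 <- rho0 %||% pure_density(amplitude_state(c(1, 0)))
  tr <- open_trajectory(model, rho0, times)
  out <- dplyr::mutate(
    tr$summary,
    p_down = dplyr::pull(dplyr::filter(tr$probabilities, .data$level == 1L),
                         "probability"),
    p_up = 1 - .data$p_down
  )
  out <- dplyr::select(out, "time", "p_down", "p_up", "coherence_l1",
                       "min_eigenvalue")
  class(out) <- c("walk_trajectory", class(out))
  attr(out, "model") <- model
  out
}

#' Mean-evidence trajectories of the four lattice models
#'
#' Runs the pure Markov walk, the pure quantum walk, and the open system
#' with `G = K` and with `G = T(tau)` on an `n`-level lattice, from a
#' discrete Gaussian initial distribution centred mid-scale (its square root
#' for the quantum/open models). Returns mean-evidence curves over the grid
#' and level-probability snapshots at selected times — the package's
#' reproduction harness for the qualitative contrast between monotone Markov
#' relaxation, indefinite quantum oscillation, and the oscillate-then-settle
#' open-system behaviour.
#'
#' @param n Lattice size (default 101).
#' @param alpha,beta Markov rates (`beta > alpha` gives positive drift).
#' @param b,sigma Hamiltonian linear-potential slope and coupling.
#' @param w Mixing weight for the two open-system models.
#' @param tau Transition-coupling time scale.
#' @param times Time grid.
#' @param init_sd Gaussian initial spread in level units (default `n / 10`).
#' @param snapshot_times Times at which to keep full level distributions.
#' @param rtol,atol ODE tolerances for the open-system integrations.
#' @return An object of class `evidence_trajectory`: list with `means`
#'   (tibble: model, time, mean_evidence), `snapshots` (tibble: model, time,
#'   level, probability), `positivity` (tibble: model, time,
#'   min_eigenvalue), and `invariant_mean` (the Markov stationary mean).
#' @export
evidence_trajectory <- function(n = 101, alpha = 1, beta = 2, b = 2,
                                sigma = 1, w = 0.5, tau = 1,
                                times = seq(0, 30, by = 0.25),
                                init_sd = n / 10,
                                snapshot_times = max(times),
                                rtol = 1e-8, atol = 1e-10) {
  sc <- evidence_scale(n)
  K <- markov_generator(n, alpha, beta)
  H <- hamiltonian_walk(n, b = b, sigma = sigma)
  phi0 <- gaussian_probability(sc, sd = init_sd)
  psi0 <- probability_to_amplitude(phi0)
  rho0 <- pure_density(psi0)

  if (times[1] > 0) times <- c(0, times)

  # pure Markov: expm per grid time
  markov_probs <- purrr::map_dfr(times, function(t) {
    p <- propagate_markov(K, phi0, t)
    tibble::tibble(model = "markov", time = t, level = 0:(n - 1),
                   probability = as.numeric(p))
  })
  # pure quantum: one eigendecomposition, amplitudes per grid time
  e <- eigen(H$matrix, symmetric = TRUE)
  c0 <- as.vector(t(Conj(e$vectors + 0i)) %*% unclass(psi0))
  quantum_probs <- purrr::map_dfr(times, function(t) {
    a <- as.vector((e$vectors + 0i) %*% (exp(-1i * e$values * t) * c0))
    tibble::tibble(model = "quantum", time = t, level = 0:(n - 1),
                   probability = Mod(a)^2)
  })
  # open systems: one ODE integration each over the whole grid
  open_k <- open_trajectory(open_system(H, lindblad_from_generator(K), w),
                            rho0, times, scale = sc, rtol = rtol, atol = atol)
  open_t <- open_trajectory(open_system(H, lindblad_from_transition(K, tau), w),
                            rho0, times, scale = sc, rtol = rtol, atol = atol)

  probs <- dplyr::bind_rows(
    markov_probs, quantum_probs,
    dplyr::mutate(open_k$probabilities, model = "open_gk", .before = 1),
    dplyr::mutate(open_t$probabilities, model = "open_gt", .before = 1)
  )
  means <- probs |>
    dplyr::group_by(.data$model, .data$time) |>
    dplyr::summarise(
      mean_evidence = sum(sc$values[.data$level + 1L] * .data$probability),
      .groups = "drop"
    )
  snaps <- dplyr::filter(probs, .data$time %in%
                           times[vapply(snapshot_times, function(ts)
                             which.min(abs(times - ts)), integer(1))])
  positivity <- dplyr::bind_rows(
    dplyr::mutate(dplyr::select(open_k$summary, "time", "min_eigenvalue"),
                  model = "open_gk", .before = 1),
    dplyr::mutate(dplyr::select(open_t$summary, "time", "min_eigenvalue"),
                  model = "open_gt", .before = 1)
  )
  structure(
    list(means = means, snapshots = snaps, positivity = positivity,
         invariant_mean = mean_evidence(invariant_distribution(K), sc),
         scale = sc),
    class = "evidence_trajectory"
  )
}

#' @export
print.evidence_trajectory <- function(x, ...) {
  cat("<evidence_trajectory> ", x$scale$n_levels, " levels, models: ",
      paste(unique(x$means$model), collapse = ", "),
      "; Markov invariant mean = ", format(x$invariant_mean, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Number of direction reversals of a numeric series
#'
#' Counts sign changes of the increments (ignoring increments below `tol`) —
#' used to distinguish monotone relaxation from oscillation.
#'
#' @param x Numeric series.
#' @param tol Increment magnitude below which a step counts as flat.
#' @export
direction_reversals <- function(x, tol = 1e-9) {
  d <- diff(x)
  d <- d[abs(d) > tol]
  if (length(d) < 2) return(0L)
  sum(diff(sign(d)) != 0)
}

#' Interference (Chapman-Kolmogorov violation) statistic
#'
#' Compares the confidence distribution at `t2` between the two paradigm
#' conditions: *measured* — the first-stage choice is measured at `t1` and
#' confidence outcomes are pooled over the (unrecorded) choice via the
#' unnormalised Lueders joint probabilities; *unmeasured* — no first-stage
#' measurement. Markov dynamics satisfy the Chapman-Kolmogorov equation, so
#' the two distributions coincide and the L1 statistic is zero; quantum
#' dynamics are changed by the intermediate collapse, making the statistic
#' generically positive.
#'
#' @param model An [open_system()], [markov_generator()], or
#'   [hamiltonian_walk()] (pure quantum).
#' @param state0 Initial state matching the model (`density_state` for open
#'   and quantum models, `probability_state` for a Markov generator; an
#'   `amplitude_state` is accepted and converted to its pure density).
#' @param design A [paradigm_design()].
#' @param method Propagation route for open-system models.
#' @return An object of class `interference`: list with `distributions`
#'   (tibble: confidence, p_measured, p_unmeasured) and `statistic`
#'   (the L1 distance).
#' @export
interference_statistic <- function(model, state0, design,
                                   method = c("expm", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "paradigm_design"))
  labs <- vapply(design$confidence, function(m) m$label, character(1))

  if (inherits(model, "markov_generator")) {
    stopifnot(inherits(state0, "probability_state"))
    pm <- vapply(design$confidence, function(mc)
      sum(vapply(design$choice, function(ch)
        joint_response_probability(model, state0, list(ch, mc),
                                   c(design$t1, design$t2)), numeric(1))),
      numeric(1))
    pu <- vapply(design$confidence, function(mc)
      joint_response_probability(model, state0, list(mc), design$t2),
      numeric(1))
  } else {
    if (inherits(state0, "amplitude_state")) state0 <- pure_density(state0)
    stopifnot(inherits(state0, "density_state"))
    if (inherits(model, "hamiltonian")) {
      joint <- function(projs, times)
        joint_response_probability_quantum(model, state0, projs, times)
    } else {
      stopifnot(inherits(model, "open_system"))
      joint <- function(projs, times)
        joint_response_probability_open(model, state0, projs, times,
                                        method = method)
    }
    pm <- vapply(design$confidence, function(mc)
      sum(vapply(design$choice, function(ch)
        joint(list(ch, mc), c(design$t1, design$t2)), numeric(1))),
      numeric(1))
    pu <- vapply(design$confidence, function(mc)
      joint(list(mc), design$t2), numeric(1))
  }
  structure(
    list(distributions = tibble::tibble(confidence = labs, p_measured = pm,
                                        p_unmeasured = pu),
         statistic = sum(abs(pm - pu))),
    class = "interference"
  )
}

#' @export
print.interference <- function(x, ...) {
  cat("<interference> L1 Chapman-Kolmogorov statistic = ",
      format(x$statistic, digits = 6), " over ",
      nrow(x$distributions), " confidence outcomes\n", sep = "")
  invisible(x)
}
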