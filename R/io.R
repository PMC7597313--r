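#' Run configuration
#'
#' A validated specification of one model run, mirroring the constructor
#' arguments: lattice size, Markov rates, Hamiltonian potential, mixing
#' weight, coupling choice, time grid, propagation method, and seed.
#' Unknown keys are rejected so that typos fail loudly.
#'
#' `read_run_config()` loads a YAML or JSON file; `run_config()` builds the
#' same object programmatically. Defaults are filled for every omitted key
#' and recorded in the returned object, so a run is fully reproducible from
#' the object alone.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @param ... Named configuration values (see Details).
#' @details Recognised keys and defaults: `n_levels` (2), `alpha` (1),
#'   `beta` (2), `hamiltonian` (list `a = 0, b = 0, c = 0, sigma = 1`), `w`
#'   (0.5), `coupling` (list `kind = "generator", tau = 1`), `t_grid` (list
#'   `from = 0, to = 10, by = 0.1`), `init` (list `center`, `sd`; defaults
#'   mid-scale, `n_levels / 10`), `method` ("ode" for `n_levels > 30`, else
#'   "expm"), `seed` (1).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  user <- list(...)
  defaults <- list(
    n_levels = 2L,
    alpha = 1, beta = 2,
    hamiltonian = list(a = 0, b = 0, c = 0, sigma = 1),
    w = 0.5,
    coupling = list(kind = "generator", tau = 1),
    t_grid = list(from = 0, to = 10, by = 0.1),
    init = list(center = NULL, sd = NULL),
    method = NULL,
    seed = 1L
  )
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  for (blk in c("hamiltonian", "coupling", "t_grid", "init")) {
    if (!is.null(user[[blk]])) {
      bad <- setdiff(names(user[[blk]]), names(defaults[[blk]]))
      if (length(bad))
        abort(sprintf("unknown key(s) in `%s`: %s", blk,
                      paste(bad, collapse = ", ")))
      user[[blk]] <- modifyList(defaults[[blk]], user[[blk]])
    }
  }
  cfg <- modifyList(defaults, user)
  cfg$n_levels <- as.integer(cfg$n_levels)
  if (cfg$n_levels < 2L) abort("config: n_levels must be >= 2")
  if (cfg$alpha < 0 || cfg$beta < 0 || cfg$alpha + cfg$beta <= 0)
    abort("config: rates must be non-negative with alpha + beta > 0")
  if (cfg$w < 0 || cfg$w > 1) abort("config: w must lie in [0, 1]")
  if (!cfg$coupling$kind %in% c("generator", "transition", "scaled_transition"))
    abort("config: coupling kind must be generator/transition/scaled_transition")
  if (cfg$coupling$kind != "generator" && cfg$coupling$tau <= 0)
    abort("config: coupling tau must be positive")
  if (is.null(cfg$method)) cfg$method <- if (cfg$n_levels > 30) "ode" else "expm"
  if (!cfg$method %in% c("expm", "ode")) abort("config: bad method")
  if (is.null(cfg$init$center)) cfg$init$center <- (cfg$n_levels - 1) / 2
  if (is.null(cfg$init$sd)) cfg$init$sd <- cfg$n_levels / 10
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)  # YAML is a JSON superset; both formats parse
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> n_levels = ", x$n_levels, ", w = ", x$w, ", coupling ",
      x$coupling$kind, ", method ", x$method, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Instantiate the model objects described by a configuration
#'
#' @param config A [run_config()].
#' @return List with `scale`, `K`, `H`, `G`, `model`, `phi0`, `psi0`,
#'   `rho0`, `times`.
#' @export
build_from_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- evidence_scale(config$n_levels)
  K <- markov_generator(config$n_levels, config$alpha, config$beta)
  hp <- config$hamiltonian
  H <- hamiltonian_walk(config$n_levels, a = hp$a, b = hp$b, c = hp$c,
                        sigma = hp$sigma)
  G <- switch(config$coupling$kind,
              generator = lindblad_from_generator(K),
              transition = lindblad_from_transition(K, config$coupling$tau),
              scaled_transition =
                lindblad_from_scaled_transition(K, config$coupling$tau))
  phi0 <- gaussian_probability(sc, center = config$init$center,
                               sd = config$init$sd)
  psi0 <- probability_to_amplitude(phi0)
  list(scale = sc, K = K, H = H, G = G,
       model = open_system(H, G, config$w),
       phi0 = phi0, psi0 = psi0, rho0 = pure_density(psi0),
       times = seq(config$t_grid$from, config$t_grid$to, by = config$t_grid$by))
}

#' Serialize states and trajectories
#'
#' Probability vectors write to long-format CSV (`level`, `probability`);
#' complex states and densities write to JSON with paired real/imaginary
#' parts, at full double precision, and round-trip exactly.
#'
#' @param state A state object.
#' @param path Output file path.
#' @name serialization
NULL

#' @rdname serialization
#' @export
write_state_csv <- function(state, path) {
  readr::write_csv(tibble::as_tibble(state), path)
  invisible(path)
}

#' @rdname serialization
#' @export
state_to_json <- function(state) {
  if (inherits(state, "probability_state"))
    return(jsonlite::toJSON(list(type = "probability",
                                 probs = as.numeric(unclass(state))),
                            digits = NA, auto_unbox = TRUE))
  if (inherits(state, "amplitude_state")) {
    a <- unclass(state)
    return(jsonlite::toJSON(list(type = "amplitude", re = Re(a), im = Im(a)),
                            digits = NA, auto_unbox = TRUE))
  }
  if (inherits(state, "density_state")) {
    m <- unclass(state)
    return(jsonlite::toJSON(list(type = "density",
                                 re = as.data.frame(Re(m)),
                                 im = as.data.frame(Im(m))),
                            digits = NA, auto_unbox = TRUE))
  }
  abort("unsupported state type")
}

#' @rdname serialization
#' @param json JSON text produced by `state_to_json()`.
#' @export
state_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  switch(x$type,
         probability = probability_state(x$probs),
         amplitude = amplitude_state(complex(real = x$re, imaginary = x$im)),
         density = density_state(
           unname(as.matrix(x$re)) + 1i * unname(as.matrix(x$im)),
           allow_nonpositive = TRUE),
         abort("unknown serialized state type"))
}

#' Random small model instance
#'
#' Draws a random valid instance for property-style testing: a Hermitian
#' Hamiltonian with symmetrised complex Gaussian entries, a tridiagonal
#' Markov generator with positive rates, a Lindblad coupling of a random
#' kind, and a random full-rank density (normalised Wishart-type matrix
#' `A A^dagger / tr`). Bit-reproducible under a fixed seed.
#'
#' @param n_max Maximum lattice size (size drawn uniformly from `2:n_max`).
#' @param seed Integer seed.
#' @return List with `n`, `H`, `K`, `G`, `rho`, `w`.
#' @export
random_instance <- function(n_max = 6, seed = 1L) {
  if (n_max < 2) abort("`n_max` must be >= 2.")
  set.seed(seed)
  n <- sample(2:n_max, 1)
  A <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  Hm <- (A + Conj(t(A))) / 2
  H <- hamiltonian_walk(n)        # container for dims; matrix replaced below
  H$matrix <- Hm
  K <- markov_generator(n, alpha = runif(1, 0.2, 2), beta = runif(1, 0.2, 2))
  kind <- sample(c("generator", "transition", "scaled_transition"), 1)
  tau <- runif(1, 0.2, 1)
  G <- switch(kind,
              generator = lindblad_from_generator(K),
              transition = lindblad_from_transition(K, tau),
              scaled_transition = lindblad_from_scaled_transition(K, tau))
  B <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  W <- B %*% Conj(t(B))
  rho <- density_state(W / Re(sum(diag(W))))
  list(n = n, H = H, K = K, G = G, rho = rho,
       w = sample(c(0, 0.25, 0.5, 0.75, 1), 1))
}
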