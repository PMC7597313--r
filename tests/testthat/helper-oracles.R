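# Shared oracles and fixture builders for the test suite.

# Plain complex matrix view of a (possibly classed) density.
mat <- function(x) {
  x <- unclass(x)
  attr(x, "min_eigenvalue") <- NULL
  x + 0i
}

# Literal Lindblad-sum right-hand side: materialises all N^2 operators
# L_ij = |i><j| and sums the sandwich terms directly. Kept deliberately
# independent of the closed-form reduction used by the package.
literal_master_rhs <- function(model, rho) {
  H <- model$H$matrix
  G <- model$G$gamma
  w <- model$w
  n <- nrow(G)
  rho <- unclass(rho) + 0i
  out <- -1i * (1 - w) * (H %*% rho - rho %*% H)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    L <- matrix(0, n, n)
    L[i, j] <- 1
    LdL <- Conj(t(L)) %*% L
    out <- out + w * G[i, j] *
      (L %*% rho %*% Conj(t(L)) - 0.5 * (LdL %*% rho + rho %*% LdL))
  }
  out
}

# The two-level model of the worked examples: H = [[0,1],[1,1]] (linear
# potential b = 1, coupling sigma = 1) and the 2x2 generator K.
two_state_parts <- function(alpha = 1, beta = 2) {
  list(K = markov_generator(2, alpha, beta),
       H = hamiltonian_walk(2, b = 1, sigma = 1),
       scale = evidence_scale(2))
}

# Closed-form stationary densities of the two-level open system at w = 0.5.
two_state_equilibrium_gk <- function(alpha, beta) {
  s <- alpha + beta
  matrix(c(alpha / s, (beta - alpha) / s,
           (beta - alpha) / s, beta / s), 2, 2) + 0i
}

two_state_equilibrium_gt <- function(alpha, beta) {
  s <- alpha + beta
  r21 <- (1 + 1i) / 6 * (1 - 2 * alpha / s)
  matrix(c((1 + alpha / s) / 3 + 0i, r21,
           Conj(r21), (1 + beta / s) / 3 + 0i), 2, 2)
}

# Deterministic small instance with guaranteed coverage of a coupling kind
# and weight (random_instance() draws those at random).
fixed_instance <- function(seed, kind, w, n_max = 6) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  A <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  H <- hamiltonian_walk(n)
  H$matrix <- (A + Conj(t(A))) / 2
  K <- markov_generator(n, alpha = runif(1, 0.2, 2), beta = runif(1, 0.2, 2))
  tau <- runif(1, 0.2, 1)
  G <- switch(kind,
              generator = lindblad_from_generator(K),
              transition = lindblad_from_transition(K, tau),
              scaled_transition = lindblad_from_scaled_transition(K, tau))
  B <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  W <- B %*% Conj(t(B))
  list(n = n, H = H, K = K, G = G, tau = tau, w = w,
       rho = density_state(W / Re(sum(diag(W)))),
       model = open_system(H, G, w))
}

binary_design <- function(t1 = 0.4, t2 = 0.8) {
  sc <- evidence_scale(2)
  ch <- list(projector(sc, 0, "up"), projector(sc, 1, "down"))
  paradigm_design(t1, t2, ch, ch)
}
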