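test_that("coupling constructors diagnose structure, PSD status and column sums", {
  K <- markov_generator(2, 1, 2)
  gk <- lindblad_from_generator(K)
  expect_equal(gk$gamma, matrix(c(-2, 2, 1, -1), 2))
  expect_equal(coherence_decay_rates(gk), c(0, 0))
  expect_false(gk$psd)

  gt <- lindblad_from_transition(K, 50)
  expect_equal(gt$gamma, matrix(c(1, 2, 1, 2) / 3, 2), tolerance = 1e-10)
  expect_equal(coherence_decay_rates(gt), c(1, 1), tolerance = 1e-12)

  # (T(tau) - I)/tau approximates K for small tau
  K6 <- markov_generator(6, 0.8, 1.5)
  gs <- lindblad_from_scaled_transition(K6, 1e-4)
  expect_equal(gs$gamma - diag(6) / 1e-4, K6$matrix, tolerance = 1e-3)
  expect_equal(coherence_decay_rates(gs), rep(1e4, 6), tolerance = 1e-8)
  expect_equal(lindblad_from_scaled_transition(K6, 1)$gamma,
               lindblad_from_transition(K6, 1)$gamma)
  expect_true(lindblad_from_transition(K6, 0.7)$psd)
  expect_error(lindblad_from_transition(K, -1), "positive")
  expect_error(lindblad_from_scaled_transition(K, 2), "\\(0, 1\\]")
})

test_that("closed-form master equation equals the literal Lindblad-operator sum", {
  for (s in 1:8) {
    kind <- c("generator", "transition", "scaled_transition")[(s %% 3) + 1]
    w <- c(0, 0.25, 0.5, 0.75)[(s %% 4) + 1]
    inst <- fixed_instance(s, kind, w)
    d_closed <- master_rhs(inst$model, inst$rho)
    d_literal <- literal_master_rhs(inst$model, inst$rho)
    expect_equal(d_closed, d_literal, tolerance = 1e-12)
    expect_equal(Re(sum(diag(d_closed))), 0, tolerance = 1e-12)
    expect_equal(Im(sum(diag(d_closed))), 0, tolerance = 1e-12)
  }
})

test_that("master equation reduces to the dynamics printed for the two-level example", {
  # w = 0.5, G = K: 2 d rho/dt = -i[H, rho] + [[a r22 - b r11, 0], [0, -(a r22 - b r11)]]
  set.seed(9)
  parts <- two_state_parts(alpha = 1, beta = 2)
  m <- open_system(parts$H, lindblad_from_generator(parts$K), 0.5)
  B <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2)
  W <- B %*% Conj(t(B)); rho <- mat(density_state(W / Re(sum(diag(W)))))
  H <- parts$H$matrix
  diss <- diag(c(1 * rho[2, 2] - 2 * rho[1, 1],
                 -(1 * rho[2, 2] - 2 * rho[1, 1])))
  expect_equal(2 * master_rhs(m, rho),
               -1i * (H %*% rho - rho %*% H) + diss, tolerance = 1e-12)

  # w = 0: exactly the unitary commutator flow
  m0 <- open_system(parts$H, lindblad_from_generator(parts$K), 0)
  expect_equal(master_rhs(m0, rho), -1i * (H %*% rho - rho %*% H),
               tolerance = 1e-14)

  # w = 1, G = T(tau): diagonal flow (T - I) diag(rho); off-diagonals -rho_kl
  K6 <- markov_generator(5, 0.9, 1.6)
  Tm <- transition_matrix(K6, 0.8)$matrix
  m1 <- open_system(hamiltonian_walk(5, b = 1), lindblad_from_transition(K6, 0.8), 1)
  B <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5)
  W <- B %*% Conj(t(B)); rho5 <- mat(density_state(W / Re(sum(diag(W)))))
  d <- master_rhs(m1, rho5)
  expect_equal(diag(d), (Tm - diag(5)) %*% diag(rho5) |> as.vector(),
               tolerance = 1e-12)
  off <- d + 0; diag(off) <- 0
  expected_off <- -rho5; diag(expected_off) <- 0
  expect_equal(off, expected_off, tolerance = 1e-12)

  # w = 1, G = K: off-diagonal derivative is zero
  mK <- open_system(hamiltonian_walk(5), lindblad_from_generator(K6), 1)
  dK <- master_rhs(mK, rho5); diag(dK) <- 0
  expect_equal(dK, matrix(0i, 5, 5), tolerance = 1e-13)
})

test_that("superoperator action equals the master right-hand side after vectorisation", {
  for (s in 1:10) {
    kind <- c("generator", "transition", "scaled_transition")[(s %% 3) + 1]
    w <- c(0, 0.25, 0.5, 0.75, 1)[(s %% 5) + 1]
    inst <- fixed_instance(100 + s, kind, w)
    Lm <- superoperator(inst$model)$matrix
    lhs <- as.vector(Lm %*% as.vector(unclass(inst$rho)))
    rhs <- as.vector(master_rhs(inst$model, inst$rho))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # w = 0 Kronecker form
  inst <- fixed_instance(7, "transition", 0)
  Lm <- superoperator(inst$model)$matrix
  H <- inst$H$matrix; I <- diag(inst$n)
  expect_equal(Lm, -1i * (kronecker(I, H) - kronecker(t(H), I)),
               tolerance = 1e-12)
})

test_that("the two propagation routes agree and preserve trace and Hermiticity", {
  for (s in 1:6) {
    kind <- c("generator", "transition", "scaled_transition")[(s %% 3) + 1]
    w <- c(0.25, 0.5, 0.75)[(s %% 3) + 1]
    inst <- fixed_instance(200 + s, kind, w)
    t <- 0.8
    a <- suppressWarnings(propagate_open(inst$model, inst$rho, t, "expm"))
    b <- suppressWarnings(propagate_open(inst$model, inst$rho, t, "ode"))
    expect_equal(mat(a), mat(b), tolerance = 1e-6)
    expect_equal(Re(sum(diag(mat(a)))), 1, tolerance = 1e-8)
    expect_equal(mat(a), Conj(t(mat(a))), tolerance = 1e-8)
  }
})

test_that("open flow reduces to the unitary walk at w = 0 and to the Markov walk at w = 1 with G = K", {
  inst <- fixed_instance(42, "generator", 0, n_max = 5)
  t <- 1.3
  expect_equal(mat(propagate_open(inst$model, inst$rho, t, "expm")),
               mat(propagate_unitary(inst$H, inst$rho, t)),
               tolerance = 1e-8)
  m1 <- open_system(inst$H, inst$G, 1)
  rho_t <- propagate_open(m1, inst$rho, t, "expm")
  phi_t <- propagate_markov(inst$K, probability_state(Re(diag(unclass(inst$rho)))), t)
  expect_equal(Re(diag(mat(rho_t))), as.numeric(phi_t), tolerance = 1e-8)
  # off-diagonals frozen under G = K at w = 1
  off0 <- mat(inst$rho); diag(off0) <- 0
  offt <- mat(rho_t); diag(offt) <- 0
  expect_equal(offt, off0, tolerance = 1e-8)
})

test_that("coherences decay exponentially at the coupling's column-sum rate", {
  inst <- fixed_instance(55, "transition", 1, n_max = 5)
  t <- 1.7
  rho_t <- mat(propagate_open(inst$model, inst$rho, t, "expm"))
  rho_0 <- unclass(inst$rho)
  for (k in 1:inst$n) for (l in 1:inst$n) if (k != l)
    expect_equal(Mod(rho_t[k, l]), Mod(rho_0[k, l]) * exp(-t),
                 tolerance = 1e-8)
  # scaled transition: rate 1/tau
  Gs <- lindblad_from_scaled_transition(inst$K, 0.25)
  ms <- open_system(inst$H, Gs, 1)
  rho_s <- mat(propagate_open(ms, inst$rho, 0.5, "expm"))
  expect_equal(Mod(rho_s[1, 2]), Mod(rho_0[1, 2]) * exp(-0.5 / 0.25),
               tolerance = 1e-8)
})

test_that("diagonal flow under G = T(tau) matches the rescaled Markov time-scale law", {
  inst <- fixed_instance(61, "transition", 1, n_max = 6)
  tau <- inst$G$tau
  t <- 2.3
  rho_t <- mat(propagate_open(inst$model, inst$rho, t, "expm"))
  # (T(tau) - I)/tau flow evaluated at tau * t gives the same diagonals
  A <- (inst$G$gamma - diag(inst$n)) / tau
  phi <- as.vector(as.matrix(Matrix::expm(A * (tau * t))) %*%
                     Re(diag(unclass(inst$rho))))
  expect_equal(Re(diag(rho_t)), phi, tolerance = 1e-8)
})

test_that("equilibrium solver recovers the two-level closed forms", {
  parts <- two_state_parts(1, 2)
  eq_k <- equilibrium_density(open_system(parts$H,
                                          lindblad_from_generator(parts$K), 0.5))
  expect_equal(mat(eq_k), two_state_equilibrium_gk(1, 2),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(mat(eq_k), matrix(c(1, 1, 1, 2) / 3, 2) + 0i,
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_gte(attr(eq_k, "min_eigenvalue"), 0)   # alpha beta >= (beta - alpha)^2

  eq_t <- equilibrium_density(open_system(parts$H,
                                          lindblad_from_transition(parts$K, 40), 0.5))
  expect_equal(mat(eq_t), two_state_equilibrium_gt(1, 2),
               ignore_attr = TRUE, tolerance = 1e-7)
  expect_equal(Re(diag(mat(eq_t))), c(4, 5) / 9, tolerance = 1e-7)
  expect_equal(mat(eq_t)[2, 1], (1 + 1i) / 18, tolerance = 1e-7)

  # degenerate stationary set of the purely unitary flow is reported
  expect_warning(
    out <- equilibrium_density(open_system(parts$H,
                                           lindblad_from_generator(parts$K), 0)),
    "dimension")
  expect_null(out)
})

test_that("positivity violations under a non-PSD coupling are detected and reported", {
  # alpha beta < (beta - alpha)^2: the G = K equilibrium is not PSD
  parts <- two_state_parts(1, 5)
  m <- open_system(parts$H, lindblad_from_generator(parts$K), 0.5)
  rho0 <- pure_density(amplitude_state(c(1, 0)))
  expect_warning(rho_t <- propagate_open(m, rho0, 30, "expm"),
                 "positivity violated")
  expect_lt(attr(rho_t, "min_eigenvalue"), -1e-8)
  # trace is still conserved even outside the density cone
  expect_equal(Re(sum(diag(mat(rho_t)))), 1, tolerance = 1e-8)
  # the PSD transition coupling never violates positivity
  mt <- open_system(parts$H, lindblad_from_transition(parts$K, 1), 0.5)
  for (t in c(0.5, 2, 10))
    expect_gte(attr(propagate_open(mt, rho0, t, "expm"), "min_eigenvalue"),
               -1e-8)
})

test_that("sequential open-system measurement reduces to its quantum and Markov limits", {
  sc <- evidence_scale(4)
  inst <- fixed_instance(77, "generator", 0, n_max = 4)
  n <- inst$n; sc <- evidence_scale(n)
  projs <- list(projector(sc, 0:(n %/% 2 - 1)), projector(sc, 0))
  times <- c(0.5, 1.1)
  expect_equal(
    joint_response_probability_open(inst$model, inst$rho, projs, times),
    joint_response_probability_quantum(inst$H, inst$rho, projs, times),
    tolerance = 1e-8)
  # w = 1, G = K: classical joint probability on the diagonal
  m1 <- open_system(inst$H, inst$G, 1)
  phi0 <- probability_state(Re(diag(unclass(inst$rho))))
  expect_equal(
    joint_response_probability_open(m1, inst$rho, projs, times),
    joint_response_probability(inst$K, phi0, projs, times),
    tolerance = 1e-8)
  # identity projectors give probability 1
  ident <- projector(sc, 0:(n - 1))
  expect_equal(joint_response_probability_open(inst$model, inst$rho,
                                               list(ident, ident), times), 1,
               tolerance = 1e-10)
})

test_that("open trajectories track trace, coherence and positivity over a grid", {
  inst <- fixed_instance(88, "transition", 0.5, n_max = 5)
  tr <- open_trajectory(inst$model, inst$rho, seq(0, 3, by = 0.5))
  expect_equal(tr$summary$trace, rep(1, nrow(tr$summary)), tolerance = 1e-8)
  expect_true(all(tr$summary$min_eigenvalue >= -1e-8))
  # coherence shrinks under a decohering coupling
  expect_lt(tail(tr$summary$coherence_l1, 1), tr$summary$coherence_l1[1])
  expect_equal(nrow(tr$probabilities), 7 * inst$n)
})
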