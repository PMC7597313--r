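test_that("paradigm designs demand complete partitions and ordered times", {
  sc <- evidence_scale(4)
  ch <- list(projector(sc, 0:1, "low"), projector(sc, 2:3, "high"))
  expect_s3_class(paradigm_design(0.5, 1, ch, ch), "paradigm_design")
  expect_error(paradigm_design(1, 0.5, ch, ch), "t1 < t2")
  expect_error(paradigm_design(0.5, 1, ch[1], ch), "partition")
})

test_that("two-level trajectory relaxes to the coupling-dependent equilibrium", {
  # w = 1, G = K is the pure Markov relaxation to beta/(alpha+beta)
  tr1 <- two_state_trajectory(1, 2, w = 1, coupling = "generator",
                              times = seq(0, 10, by = 0.25))
  expect_true(all(diff(tr1$p_down) > -1e-8))
  expect_equal(tail(tr1$p_down, 1), 2 / 3, tolerance = 1e-6)
  # coherence-free: the classical trajectory has no oscillation
  expect_equal(direction_reversals(tr1$p_down, tol = 1e-8), 0)

  # w = 0.5, G = K settles at the same Markov asymptote
  tr2 <- two_state_trajectory(1, 2, w = 0.5, coupling = "generator",
                              times = c(seq(0, 5, by = 0.25), 100))
  expect_equal(tail(tr2$p_down, 1), 2 / 3, tolerance = 1e-4)
  # but oscillates on the way
  expect_gte(direction_reversals(tr2$p_down[tr2$time <= 5], tol = 1e-6), 1)

  # w = 0.5, G = T(large tau) settles strictly below, at (1/3)(1 + b/(a+b))
  tr3 <- two_state_trajectory(1, 2, w = 0.5, coupling = "transition", tau = 40,
                              times = c(seq(0, 5, by = 0.5), 100))
  expect_equal(tail(tr3$p_down, 1), 5 / 9, tolerance = 1e-4)
  expect_lt(tail(tr3$p_down, 1), 2 / 3)
})

test_that("interference statistic separates Markov from quantum dynamics", {
  # Markov dynamics: exactly Chapman-Kolmogorov, statistic ~ 0
  set.seed(12)
  for (rep in 1:3) {
    n <- sample(3:6, 1)
    sc <- evidence_scale(n)
    K <- markov_generator(n, runif(1, 0.4, 2), runif(1, 0.4, 2))
    phi0 <- probability_state(prop.table(runif(n)))
    cut <- sample(seq_len(n - 1), 1)
    des <- paradigm_design(0.5, 1.2,
                           list(projector(sc, 0:(cut - 1)),
                                projector(sc, cut:(n - 1))),
                           lapply(0:(n - 1), function(j) projector(sc, j)))
    res <- interference_statistic(K, phi0, des)
    expect_lt(res$statistic, 1e-10)
  }

  # the specified two-level quantum configuration interferes strongly
  H <- hamiltonian_walk(2, sigma = 1)
  des2 <- binary_design(pi / 8, pi / 4)
  res_q <- interference_statistic(H, amplitude_state(c(1, 0)), des2)
  expect_gt(res_q$statistic, 0.01)
  # both condition columns are probability distributions
  expect_equal(sum(res_q$distributions$p_measured), 1, tolerance = 1e-10)
  expect_equal(sum(res_q$distributions$p_unmeasured), 1, tolerance = 1e-10)

  # trivial first measurement (identity) removes the interference
  sc2 <- evidence_scale(2)
  des_triv <- paradigm_design(pi / 8, pi / 4, list(projector(sc2, 0:1)),
                              list(projector(sc2, 0), projector(sc2, 1)))
  expect_lt(interference_statistic(H, amplitude_state(c(1, 0)),
                                   des_triv)$statistic, 1e-12)

  # open system at w = 1, G = K is Markov-reducible: no interference
  parts <- two_state_parts(1, 2)
  m1 <- open_system(parts$H, lindblad_from_generator(parts$K), 1)
  rho0 <- pure_density(amplitude_state(c(1, 0)))
  expect_lt(interference_statistic(m1, rho0, des2)$statistic, 1e-10)
})

test_that("synthetic paradigm sampling is exact-probability multinomial and reproducible", {
  parts <- two_state_parts(1, 2)
  G <- lindblad_from_generator(parts$K)
  m <- open_system(parts$H, G, 0.7)
  rho0 <- pure_density(amplitude_state(c(1, 0)))
  des <- binary_design()
  probs <- paradigm_probabilities(m, rho0, des)
  sums <- tapply(probs$prob, probs$condition, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-10)

  d1 <- simulate_paradigm(m, rho0, des, n_trials = 2000, seed = 31)
  d2 <- simulate_paradigm(m, rho0, des, n_trials = 2000, seed = 31)
  expect_identical(d1$count, d2$count)
  expect_equal(as.numeric(tapply(d1$count, d1$condition, sum)), c(2000, 2000))
  # empirical frequencies approach the exact probabilities
  big <- simulate_paradigm(m, rho0, des, n_trials = 1e5, seed = 32)
  expect_lt(max(abs(big$count / 1e5 - big$prob)), 0.01)
})

test_that("weight fitting is a deterministic multinomial MLE with a usable profile", {
  parts <- two_state_parts(1, 2)
  G <- lindblad_from_generator(parts$K)
  rho0 <- pure_density(amplitude_state(c(1, 0)))
  des <- binary_design()
  dat <- simulate_paradigm(open_system(parts$H, G, 0.6), rho0, des,
                           n_trials = 4000, seed = 17)
  fit <- fit_weight(dat, parts$H, G, rho0, des, grid = seq(0, 1, by = 0.02))
  expect_s3_class(fit, "weight_fit")
  expect_lt(abs(fit$w_hat - 0.6), 0.15)
  expect_false(fit$flat)
  # profile peaks at the estimate
  expect_gte(fit$loglik, max(fit$profile$loglik))
  # broom-style accessors
  expect_identical(tidy(fit), fit$profile)
  g <- glance(fit)
  expect_equal(g$n_choice_confidence, 4000L)
  expect_equal(g$n_confidence_alone, 4000L)
  # same data, same fit (determinism)
  fit2 <- fit_weight(dat, parts$H, G, rho0, des, grid = seq(0, 1, by = 0.02))
  expect_equal(fit$w_hat, fit2$w_hat)
})

test_that("estimation error shrinks as the trial count grows", {
  parts <- two_state_parts(1, 2)
  G <- lindblad_from_generator(parts$K)
  rho0 <- pure_density(amplitude_state(c(1, 0)))
  des <- binary_design()
  truth <- 0.7
  errs <- vapply(c(200, 2000, 20000), function(n) {
    dat <- simulate_paradigm(open_system(parts$H, G, truth), rho0, des,
                             n_trials = n, seed = 100 + n)
    abs(fit_weight(dat, parts$H, G, rho0, des,
                   grid = seq(0, 1, by = 0.02))$w_hat - truth)
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 1e-8)
  expect_lt(errs[3], 0.05)
})
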