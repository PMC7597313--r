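# Full dissipator weight (w = 1) with the scaled transition coupling
# G = T(tau)/tau at tau = 1e-3: approximates the continuous-time Markov walk
# on the density diagonal while keeping a positive semidefinite coupling.
n_levels: 101
alpha: 1
beta: 2
hamiltonian:
  a: 0
  b: 16
  c: 0
  sigma: 1
w: 1
coupling:
  kind: scaled_transition
  tau: 0.001
t_grid:
  from: 0
  to: 30
  by: 0.25
method: ode
seed: 1
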