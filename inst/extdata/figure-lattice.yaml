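# 101-level evidence lattice, mixed quantum-Markov dynamics (w = 0.5).
# The linear potential (b = 16, sigma = 1) makes the pure quantum walk's mean
# evidence oscillate in the 0.5-0.75 band; the Markov rates give positive
# drift and a high-evidence invariant distribution.
n_levels: 101
alpha: 1
beta: 2
hamiltonian:
  a: 0
  b: 16
  c: 0
  sigma: 1
w: 0.5
coupling:
  kind: transition
  tau: 1
t_grid:
  from: 0
  to: 150
  by: 0.5
method: ode
seed: 1
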