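# Minimal two-level example: up/down responses, H = [[0,1],[1,1]],
# K = [[-2,1],[2,-1]], equal quantum/Markov weight.
n_levels: 2
alpha: 1
beta: 2
hamiltonian:
  a: 0
  b: 1
  c: 0
  sigma: 1
w: 0.5
coupling:
  kind: generator
t_grid:
  from: 0
  to: 20
  by: 0.1
method: expm
seed: 1
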