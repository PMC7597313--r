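---
title: "Quantum-Markov open-system models of evidence accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-Markov open-system models of evidence accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openwalk)
```

## The model

A decision maker's belief is represented on an *evidence lattice* of `N`
levels; level `j` carries the likelihood value `x_j = j/(N-1)`, so the scale
runs from certain evidence against (0) through equivocal (0.5) to certain
evidence for (1). Three state representations live on this lattice:

* a **probability state** `phi` (classical): non-negative, L1-normalised;
* an **amplitude state** `psi` (quantum): complex, L2-normalised;
* a **density matrix** `rho`: Hermitian, trace one. Its diagonal holds the
  observable level probabilities; its off-diagonal *coherences* carry the
  quantum phase information that produces interference. A density combines
  epistemic uncertainty (an observer's ignorance of the state, a classical
  mixture) with ontic uncertainty (the decision maker's own superposition
  over evidence levels).

Two pure dynamics act on the lattice. The **Markov random walk**
`d phi/dt = K phi` uses a tridiagonal generator with up-rate `beta`,
down-rate `alpha` and reflecting bounds; its drift is `(beta - alpha)/2` and
it relaxes monotonically to the detailed-balance invariant distribution
`phi*_j` proportional to `(beta/alpha)^j`. The **quantum walk**
`d psi/dt = -i H psi` uses a tridiagonal Hermitian Hamiltonian whose
diagonal is a quadratic potential `mu(x) = a + b x + c x^2` evaluated at the
level values and whose off-diagonals hold a coupling `sigma`; it never
settles.

The **open system** evolves a density under the Lindblad master equation
with elementary transition operators `L_ij = |i><j|`, coefficients
`gamma_ij` forming a matrix `G`, and a weight `w` mixing the dissipator
against the unitary commutator. Three couplings connect `G` to the Markov
walk, and their column sums `c_k = sum_i gamma_ik` determine the coherence
decay `d rho_kl/dt = -(w/1) * 0.5 (c_k + c_l) rho_kl` at full dissipator
weight:

| coupling | diagonal flow at `w = 1` | coherence decay | PSD |
|---|---|---|---|
| `G = K` | `d phi/dt = K phi` (exactly Markov) | none (`c = 0`) | no |
| `G = T(tau)` | `d phi/dt = (T(tau) - I) phi` (slowed) | rate 1 | yes |
| `G = T(tau)/tau` | `(T(tau) - I)/tau phi` (approximates `K`) | rate `1/tau` | yes |

`G = K` is not positive semidefinite, so the flow can leave the density
cone. The package *diagnoses* PSD status and *reports* positivity violations
(a warning plus a recorded minimum eigenvalue) rather than forbidding the
coupling: the non-PSD choice is scientifically interesting precisely because
it reduces exactly to the Markov walk.

For the two-level system (`H = [[0,1],[1,1]]`, i.e. the linear-potential
walk with `b = sigma = 1`) the closed-form stationary states at `w = 0.5`
are

* `G = K`: diagonal `(alpha, beta)/(alpha+beta)` — the Markov asymptote —
  with real coherence `(beta - alpha)/(alpha + beta)`;
* `G = T(large tau)`: diagonal `((1 + alpha/(alpha+beta))/3,
  (1 + beta/(alpha+beta))/3)`, strictly closer to uniform than the Markov
  asymptote, with complex coherence `(1+i)/6 (1 - 2 alpha/(alpha+beta))`.

Both are recovered by the package's null-space solver and by long-time
integration (the acceptance script recomputes them at every run).

## Numerical design

**Vectorisation.** The master equation is linear in `rho`, so column-stacking
gives `d vec(rho)/dt = L vec(rho)` with an `N^2 x N^2` superoperator built
from `vec(XYZ) = (Z^T kron X) vec(Y)` (plain transpose). For
`L_ij = |i><j|` the operator sums collapse: the jump term scatters `G` onto
the vec-positions of the density diagonal and the anticommutator term is a
diagonal damping `-(c_r + c_q)/2`. `master_rhs()` evaluates the same
reduction matrix-free in `O(N^2)` plus one commutator; the test suite keeps
a literal sum over all `N^2` Lindblad operators as an independent oracle.

**Two propagation routes.** `propagate_open(method = "expm")` exponentiates
the superoperator through its real `2N^2 x 2N^2` representation
(`Matrix::expm`), practical up to roughly 30 levels; `method = "ode"`
integrates `master_rhs()` with deSolve's adaptive Adams method (defaults
`rtol = 1e-9`, `atol = 1e-11`) and never materialises the superoperator,
which is the route used for the 101-level lattice. The two routes agree
elementwise to well below `1e-6` on random instances — this dual-route check
is the package's main guard against assembly bugs.

**Equilibria.** The stationary set is the null space of the superoperator
intersected with the Hermitian, trace-one slice. The complex kernel can be
more than one-dimensional even when the physical equilibrium is unique (the
two-level `G = K` model is an example), so the solver stacks the real
representation with explicit Hermiticity constraints, extracts the joint
null space by SVD, demands a unique Hermitian ray, and normalises the trace.
A degenerate Hermitian stationary set (e.g. any `w = 0` model, whose
stationary states are all densities commuting with `H`) is reported with its
dimension.

**Measurement.** Responses are diagonal 0/1 projectors; a confidence rating
is a complete partition of the lattice into contiguous bins (21 bins on 101
levels by default — the mapping of ratings to projectors is a package
convention, single-level projectors being the finest case). Sequential
(joint) probabilities follow the Lüders rule with *unnormalised*
intermediate states; renormalisation happens only when a conditional
distribution is explicitly requested. Validation tolerances (1e-12 state
norms, 1e-10 Hermiticity/trace, -1e-8 minimum eigenvalue) are package
constants overridable via `options(openwalk.tolerances = ...)`.

## The synthetic paradigm and what it does (not) show

`simulate_paradigm()` emulates the two-condition choice-confidence design:
in one condition a binary choice is measured at `t1` and a confidence
rating at `t2`; in the other only the confidence rating is taken. Trial
counts are multinomial draws from the *exact* model outcome probabilities,
so `fit_weight()`'s multinomial likelihood is deterministic given the data
(dense grid in `w` at resolution 0.01, then golden-section refinement).
The default two-level recovery design uses `t1 = 0.4`, `t2 = 0.8`, chosen by
maximising the sensitivity `sum |dp/dw|` of the outcome probabilities over a
small grid of candidate times before any recovery was attempted; early
measurement times are more informative because the quantum component's
signature decays as the dissipator takes over. At `1e4` trials per condition
the weight is recovered to within a few hundredths.

The generator samples from the model itself, so recovery results demonstrate
*internal* consistency (the estimator works when the family is correctly
specified); they say nothing about model misfit, response-time data, or the
trial-to-trial dependencies real participants exhibit.

## The lattice example and its parameters

`evidence_trajectory()` compares four models on the 101-level lattice from a
discrete Gaussian initial distribution centred mid-scale (spread `N/10`
levels; the amplitude state is its square root): pure Markov, pure quantum,
open with `G = K`, open with `G = T(1)`, all at `w = 0.5`. The shipped
parameters are `alpha = 1, beta = 2` (positive drift; invariant mean 0.99)
and `b = 16, sigma = 1`. The steep linear potential puts the quantum walk in
the tilted (Wannier-Stark) regime: the mean evidence oscillates in the band
`[0.5, 0.75]` (amplitude `4 sigma/b = 0.25`) with period
`2 pi (N-1)/b ≈ 39`, so a grid to `t = 150` shows several full oscillations.
The qualitative contrast is: Markov monotone to its asymptote; quantum
oscillating indefinitely; `G = T(1)` oscillating first and settling strictly
below the Markov asymptote.

One stated property of the `G = K` open system is *not* reproduced on this
lattice: although its unique stationary state provably has the Markov
invariant on the diagonal (stationarity forces `[H, rho*] = 0` and
`K diag(rho*) = 0`), the approach to it is astronomically slow. Because
`G = K` has zero coherence decay, relaxation is only indirect; exact
spectra of the superoperator at `N = 15..41` show the slowest nonzero modes
shrinking from `~1e-4` to below `1e-8` as `N` grows (algebraically in the
delocalised regime, exponentially in the tilted regime), giving relaxation
horizons beyond `1e5` time units at `N = 101`. Direct integration to
`t = 600` confirms the mean evidence keeps wandering by about `±0.2`. The
corresponding trajectory assertion in the acceptance suite therefore fails
by design at the feasible horizon `t = 150`; the equilibrium identity is
verified instead at small `N`, where both the null-space solver and
long-time integration reach it. Anyone fitting the `G = K` variant on large
lattices should be aware that "converges to the Markov equilibrium" is an
asymptotic statement about an impractically long time scale.

Problem sizes used by the shipped tests and the acceptance script: random
instances at `N <= 6` for the dual-route and oracle checks (50 instances),
two-level closed forms for all equilibrium checks (21 rate pairs), and a
single `t = 0..150` grid at `rtol = 1e-7` for the 101-level comparison.

## Known limitations

* Time-dependent `H` or `G`, non-Markovian master equations, and a
  derivation from an explicit system-plus-environment unitary are out of
  scope.
* First-passage (absorbing-boundary) decision-time distributions are not
  modelled; all measurements happen at fixed times.
* The dense superoperator exponential is quadratic in memory
  (`N^2 x N^2`); use the ODE route beyond ~30 levels.
* With the non-PSD coupling `G = K` the flow can and does leave the density
  cone for some rate combinations (e.g. `alpha = 1, beta = 5` at
  `w = 0.5`); the package reports this rather than preventing it.
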