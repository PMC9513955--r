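---
title: "Polynomial superlevel set representations of multistationarity regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial superlevel set representations of multistationarity regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssreg)
```

## The solution-count map and its representations

Let `f_k(x) = 0` be the steady-state system of a reaction network, with
parameters `k` (rate constants and conservation totals) ranging over a box
`B ⊂ R^r`. The object of interest is the solution-count map `Φ(k)`, the
number of distinct positive solutions at `k`, and in particular its
superlevel set `{k : Φ(k) >= 2}` — the multistationarity region. `pssreg`
treats a system abstractly as a `parametric_system`: a dimension `r`, a
domain box, and a counter `k -> Φ(k)`. Every built-in example reduces the
counter to the distinct positive roots of a univariate polynomial, but any
user routine with this signature plugs in.

Three representations of `Φ` are supported.

* **Sampling representation** (`build_sampling_representation`): `n` uniform
  draws from `B` with their counts. Simple, embarrassingly parallel, and the
  natural input for the point-constrained fit.
* **Rectangular representation**
  (`build_rectangular_representation`): an equal grid over `B`, each cell
  carrying the average count of `samples_per_cell` uniform draws from it.
  Cells are ordered row-major with the first axis fastest, so a fixed seed
  reproduces every cell average exactly. `threshold_cells(rep, u = 2)`
  extracts the cells averaging at least `u`.
* **Bisection decompositions** (`two_value_bisection`,
  `two_step_bisection`): adaptive splitting of `B` guided by an
  expected-count oracle, described below. They typically need far fewer
  oracle evaluations than a full grid at comparable resolution.

## The superlevel-set fit

Given the parameter box `B` and a target `K` (a union of rectangles `K_i`
or a finite point set), the package computes the polynomial `p` of even
total degree `d` minimising `∫_B p(k) dk` subject to `p >= 0` on `B` and
`p >= 1` on `K`. The minimal-integral property is what makes `U(p) = {p >= 1}`
an approximation from outside that tightens as `d` grows, rather than an
arbitrary separating surface.

The objective is linear in the coefficients: `∫_B p = Σ_α c_α ∫_B k^α`, and
the moments `∫_B k^α` have the closed form
`Π_j (b_j^{α_j+1} − a_j^{α_j+1})/(α_j+1)` (`monomial_integral`). Positivity
of a polynomial `q` on a box `[a, b]` is enforced by the interval
certificate

```
q = σ0 + Σ_j s_j (k_j − a_j)(b_j − k_j),   σ0 ∈ Σ_{2h},  s_j ∈ Σ_{2h−2},
```

with `h = d/2` and `Σ_{2h}` the sums of squares of degree `≤ 2h`. One
certificate is assembled for `p` on `B` and one for `p − 1` on each `K_i`;
in point mode the `K` side is instead the linear constraints `p(a_i) >= 1`.
Matching coefficients symbolically links the Gram matrices of the
certificates to the `c_α`, giving a block-diagonal semidefinite program
whose blocks have dimension `C(r+h, h)` — 9x9 in the largest case exercised
here (degree 2 in 8 parameters, 45 coefficients). Requiring `d` even is
structural: the certificate degrees cannot match for odd `d`.

### The conic solver

No semidefinite programming backend is available to this package, so it
carries a small dense solver (`solve_block_sdp`): an infeasible-start
primal-dual path-following method with the HKM search direction and a
Mehrotra predictor-corrector, with per-constraint normalisation, iterative
refinement on the Schur solves, and an adaptive retry at damped step
lengths. For the problem sizes above it converges to relative gaps around
`1e-10` in 10–40 iterations. The sampled-positivity mode is a linear
program and uses a matching inequality-form interior-point routine
(`solve_lp_ineq`) whose normal equations are only
`C(r+d, d) x C(r+d, d)`.

Two numerical behaviours are worth knowing:

* **Rescaling is on by default** (`pss_options(rescale = TRUE)`). Parameter
  boxes in applications routinely mix scales (the autoregulatory example
  has edges `5e-4` and `2`); the program is assembled on the unit box and
  the polynomial composed back exactly at coefficient level
  (`affine_compose`), which preserves the objective up to the volume factor
  and repairs otherwise severe ill-conditioning.
* **Statuses are surfaced verbatim.** Higher-degree fits over many cells
  can end with status `inaccurate (...)`: the iterate is returned when its
  worst residual is below `1e-3`, and `verify_fit` — a direct grid check of
  `p >= 0` on `B` and `p >= 1` on `K` — is the arbiter of whether the fit
  is usable. Interior-point SOS solvers degrading at higher certificate
  degrees is expected behaviour, not a silent failure mode.

Every fit records the objective `∫_B p` in original coordinates, and the
containment `K ⊆ U(p)` holds to `1e-6` on every fit that reports
`optimal` (this is asserted across random geometries in the test suite).
On nested even degrees the objective is non-increasing — the feasible sets
are nested — which the tests check on a one-dimensional instance whose
optimum is known in closed form: for `B = [−1, 1]`, `K = [−0.5, 0.5]`,
`d = 2` the optimal polynomial is `(4/3)(1 − k²)` with integral `16/9`
(both constraint pairs active, constant multiplier), and for the single
point `K = {0}` it is `1 − k²` with integral `4/3`.

## Counting positive roots

All built-in systems reduce counting steady states to counting distinct
positive real roots of one univariate polynomial
(`count_positive_roots_univariate`). Roots are computed as eigenvalues of
the companion matrix of the coefficient-normalised monic polynomial.
Because the matrix is real, LAPACK returns real eigenvalues with imaginary
part exactly zero and complex ones in exact conjugate pairs; this
classification is markedly more robust near folds than complex root
finders, which can return a real root with a small spurious imaginary part
and no conjugate partner. The tolerances are: a root is real when
`|Im z| <= 1e-8 (1 + |z|)`, positive when `Re z > 1e-9`, and real positive
roots closer than `1e-6` (relative) are merged — solutions are counted as a
set, without multiplicity. Coincident roots occupy a measure-zero set of
parameter space, so Monte-Carlo expectations are unaffected by the merge
convention. A Sturm-chain counter (`sturm_count_interval`) provides an
independent sign-variation cross-check at moderate degrees.

## Expected counts and the bisection searches

`expected_count` estimates `E[Φ(k)]` for `k` uniform or truncated-normal on
a box by plain Monte Carlo, with standard error and recorded seed.
Truncated-normal draws use the per-coordinate inverse CDF, so samples are
in-box by construction.

The **two-value search** handles the common bistable situation where `Φ` is
almost everywhere `n1` or `n2` (typically 1 or 3, with 2 only on the
measure-zero fold): the uniform expectation over a cell equals
`n1·Vol̄(cell ∩ L_{n1}) + n2·Vol̄(cell ∩ L_{n2})`, so an expectation within
`delta` of `n1` or `n2` certifies the cell (up to `delta`) and anything in
between forces a split into two equal halves. Splitting cycles through the
axes with recursion depth (`round-robin`; `longest-edge` is available).

Termination: a cell stops splitting when its edges, normalised by the root
box edges, are all `<= eps`. With this convention a worst-case search over
a box with edge ratio `2^m` whose oracle never becomes conclusive computes
exactly `Σ_{i=0}^{mr} 2^i` expectations — a complete binary tree of depth
`mr` — which the tests assert with equality. An alternative `min-edge`
termination (stop as soon as *any* normalised edge is small) is available
as a config option but is not the default: it abandons cells that are still
coarse along other axes, and it breaks the complete-tree call-count
identity.

The default closeness tolerance is `delta = 0.1`, matching one-decimal
reporting of Monte-Carlo expectations; `delta` must stay below half the
smallest gap between admissible counts.

The **two-step search** generalises to counts in `{n_1, ..., n_s}`. A
uniform expectation equal to some `n_i` is no longer conclusive — a
half-and-half mix of `n_{i−1}` and `n_{i+1}` produces the same mean — so a
candidate label is confirmed with a second expectation under a non-uniform
distribution on the cell. For a pure cell every distribution gives `n_i`;
for a mixed cell a randomly chosen distribution gives something else with
probability one. The package's confirmation distribution is a truncated
normal with per-coordinate standard deviation half the cell edge and, by
default, a mean drawn uniformly from the middle half of the cell.

The randomised mean is deliberate. A confirmation distribution symmetric
about the cell centre can be fooled whenever the level-set boundary passes
near that centre: the quintic example (`quintic_fixture`) provides a
concrete case. On its rectangle `B2 = [2, 2.5] x [2, 3]` the root count is
1 or 3 with the boundary running essentially through the centre; the
uniform expectation is 2.0–2.1 (the tests compute ≈ 2.05), and a
centre-symmetric truncated normal with variance 0.1 again yields ≈ 2.1 —
within `delta` of 2, so it would wrongly confirm the cell as pure. No
centred symmetric distribution on this cell can move the expectation far
from 2; an off-centre mean shifts it decisively. `truncated_normal_preset`
lets users pin a fixed confirmation distribution when reproducibility of a
specific setting matters more than the probability-one guarantee. On the
neighbouring rectangle `B1 = [0.5, 1] x [8, 9]` the count is identically 2
and the two-step search labels the whole box after two oracle calls.

`decomposition_to_K` turns the labeled cells with counts `>= u` into the
`K` of a rectangle fit, or samples points from their union
(volume-weighted) for a point fit.

## Distance to the fitted boundary

For a fitted `p` and a query point `k*`, `distance_to_boundary` minimises
`|k − k*|²` on the level set `p(k) = 1` via the Lagrangian
`F(k, λ) = |k − k*|² + λ(p(k) − 1)`. The critical-point system
`2(k − k*) + λ∇p = 0`, `p(k) = 1` is solved by damped Newton iteration
from a deterministic grid of starts over the box (5 per axis, capped at
`10^4` total; densified threefold automatically if no in-box critical point
converges), with analytic gradient and Hessian, deduplication at `1e-6` of
the box diagonal, and filtering to the box. The reported distance is the
minimum over in-box critical points, in original (unrescaled) coordinates —
Euclidean distance is only meaningful in the units the parameters live in.
Two degenerate contracts: a query point already on the level set (within
`1e-8`) returns distance 0, and a level set that does not meet the box is
an error rather than a fabricated answer. Note that when the nearest piece
of the level set exits the box, the constrained minimiser on the box
boundary is not a Lagrangian critical point; the reported value is the
critical-point minimum, matching the stated contract.

## The built-in systems

* `quintic_fixture()` — a degree-5 polynomial in one unknown with two free
  parameters, attaining 0–5 positive roots. Small enough that every
  behaviour (invariant rectangles, mixed rectangles, the two-step
  confirmation subtlety) can be checked against brute force.
* `ssystem_fixture()` — a four-species gene cascade with S-system (power
  law + Hill) kinetics; the right-hand sides are not rational functions.
  Its positive steady states correspond one-to-one with the positive roots
  of the sparse degree-73 polynomial
  `c y^73 − 144 y^64 + 256 c y^9 − 12288`, `c = (24 k1² k2 k3³)^{1/4}`,
  which by Descartes' rule of signs has 1 or 3 positive roots for every
  positive parameter choice. The fixture carries the back-map from a root
  `y` to the four concentrations and the residual of the four steady-state
  equations; the tests verify the residuals vanish (`<= 1e-6`) at every
  counted root across random parameter draws. About 53% of uniform draws
  from the domain cube `[3,7] x [1,5] x [10,14]` are multistationary.
* `lacitetr_fixture()` — a twelve-variable two-gene mutual-repression
  circuit. Ten equations are linear in one variable each; exact elimination
  through the two conservation laws leaves a quintic in one coordinate
  whose distinct positive roots are the steady states. The tests
  back-substitute every root into all twelve equations (residuals
  `<= 1e-6`) and cross-check counts by sign-change bracketing. On the
  default `(k7, k8)` box roughly 28 of 100 grid cells average two or more
  steady states.
* `autoreg_fixture()` — the bistable autoregulatory motif of the README:
  gene `X`, protein `P`, dimer `PP`, complex `XPP`, conservation
  `x1 + x4 = k8`. The ODE right-hand sides follow from the reaction scheme
  (basal expression `k1`, degradation `k2`, dimerisation `k3`/`k4`,
  binding `k5`/`k6`, enhanced expression `k7 = 46.9`); at steady state they
  collapse to the cubic `k2 c x³ − k7 k8 c x² + k2 x − k1 k8 = 0` in the
  free protein concentration, `c = k3 k5/(k4 k6)`. With the fixed rates
  above, dense quadrature puts the multistationary fraction of the default
  `(k3, k8)` box at 9.1%.
* `synthetic_region_oracle()` — piecewise-constant counts on user-supplied
  cells with closed-form expectations over any sub-box. This is the test
  double for everything stochastic: rectangular averages, both bisection
  searches (including exact recovery of dyadic regions and the worst-case
  call count), and the expectation-decomposition identity are all checked
  against it to machine precision.

## What the synthetic setups do and do not show

The fixtures share convenient properties real steady-state systems may
lack: counts come from one univariate polynomial (no numerical
continuation or homotopy failures, so the counter is effectively
noise-free), admissible counts are small, and the synthetic oracle's
regions are axis-aligned boxes (bisection cell boundaries can align with
them exactly; curved boundaries as in the quintic and autoregulatory
systems are the more representative case). Passing tests therefore
establish the correctness of the representations, fits, searches and
distance computations — not that a particular industrial-scale network's
counter is reliable, which is the user's contract to provide (`errors`,
never silent zeros, on solver failure).

## Problem sizes and tolerances used in the tests

The shipped test-suite and acceptance script run at deliberately desk-scale
sizes chosen to keep every stochastic check several standard errors wide:
1000 draws for the S-system and autoregulatory sampling fractions, 4000 to
20000 draws for quintic expectations, a 10x10 grid with 10 samples per cell
for the grid examples, and degrees 2–6 for the fits. Key tolerances:
real/positive/merge root tolerances `1e-8 / 1e-9 / 1e-6` as above; solver
target `1e-9` with `inaccurate` reporting below `1e-3`; fit verification
`feas_tol = 1e-6`; bisection `delta = 0.1`; all other real comparisons at
absolute `1e-9`.

## Known limitations

* The SOS program certifies `p >= 0` on `B` and `p >= 1` on `K`; it does
  not certify that `U(p)` excludes monostationary territory. The excess
  `Vol(U(p) − K)` shrinks with `d` in principle, but high-degree fits over
  many cells are exactly where the interior-point method degrades to
  `inaccurate` statuses; degrees beyond ~8 are not recommended with this
  solver.
* Distance is measured to the fitted boundary `{p = 1}`, not to the true
  region boundary; the gap between them is inherited from the fit.
* The truncated-normal confirmation step inherits Monte-Carlo noise; with
  `delta = 0.1` and a few hundred samples per call, mixed cells whose
  minority level set occupies only a few percent of the volume can be
  mislabeled. Increasing `n_samples` in `bisection_config` is the remedy.
* Counts are distinct-root counts. Systems with genuinely coincident
  steady states on positive-measure parameter sets (non-generic networks)
  violate the assumptions of both searches.
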