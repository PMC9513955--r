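# pssreg

Polynomial superlevel set (PSS) representations of multistationarity regions
of parametric systems.

## The problem

A chemical reaction network with mass-action (or more general power-law /
Hill) kinetics has steady states given by the positive solutions of a
polynomial or rational system `f_k(x) = 0`, whose coefficients depend on rate
constants and conservation-law totals `k = (k_1, ..., k_r)`. The network is
*multistationary* at `k` when that system has two or more positive solutions.
For experiment design one wants the whole region

```
{ k in B : #( f_k^{-1}(0) ∩ R^n_{>0} ) >= 2 }
```

inside a biologically meaningful parameter box `B` — and ideally in a form
that is cheap to store, cheap to query, and usable for "how far is my
operating point from the boundary?" questions.

Exact symbolic descriptions (cylindrical algebraic decomposition) blow up
beyond a few parameters; point clouds and grids of solution counts are easy
to compute but bulky and hard to interrogate. `pssreg` implements the
compromise: approximate the region by a grid, a point sample, or an adaptive
bisection of `B` driven by the *expected* solution count, then compress that
approximation into a single polynomial `p` of chosen even degree `d` by
solving

```
minimise    ∫_B p(k) dk
subject to  p >= 0 on B,   p >= 1 on K,
```

where `K` is the current approximation of the region (a union of rectangles
or a finite point set). The superlevel set `U(p) = { k : p(k) >= 1 }` then
contains `K`, and minimising the integral squeezes the spare volume
`Vol(U(p) - K)` toward zero as `d` grows. Membership is one polynomial
evaluation; storage is one coefficient vector of length `C(r+d, d)`; the
distance of a point `k*` from the region boundary is a Lagrange-multiplier
computation on `p(k) = 1`.

Positivity on boxes is enforced by interval sum-of-squares certificates
(`p = σ0 + Σ_j s_j (k_j - a_j)(b_j - k_j)` with `σ0`, `s_j` sums of
squares), which turn the fit into a small block-diagonal semidefinite
program; the package ships its own dense interior-point solver for it, plus
a linear-programming mode in which positivity is only sampled.

## Worked example

A bistable autoregulatory gene motif (gene + protein + dimer, with the dimer
binding the gene) is built in as `autoreg_fixture()`: two free parameters,
the dimerisation rate `k3` and the conserved gene total `k8`, on the box
`[0.0005, 0.001] x [0, 2]`.

```r
library(pssreg)

ar  <- autoreg_fixture()
rr  <- build_rectangular_representation(ar, ar$domain, 10, 10, seed = 1)
rr
#> <rectangular_representation: 100 cells (10x10), 10 samples/cell>
#>   average count range: 1 .. 3

K   <- threshold_cells(rr, 2)   # cells whose average count is >= 2
length(K)
#> [1] 11

fit <- fit_pss_from_rectangles(ar$domain, K, d = 2)
fit
#> <pss_representation: degree 2 in r=2, threshold 1>
#>   objective (integral of p over B): 0.00077780454
#>   solver status: optimal (22 iterations)
fit$polynomial
#> <dense_polynomial r=2 d=2 (6 coefficients)>
#>   +0.2304 -709.2*k1 +2.009*k2 +5.457e+05*k1^2 -314.9*k1k2 -0.7588*k2^2

verify_fit(fit, ar$domain, K)$ok     # p >= 0 on B and p >= 1 on every cell
#> [1] TRUE
pss_member(fit, c(0.00075, 1.0))     # is this operating point multistationary?
#> [1] TRUE
distance_to_boundary(fit, c(0.0008, 0.25))
#> <distance_result: distance 0.75000001>
#>   nearest point: ( 0.0009383695, 0.9999999991 )
#>   critical points found: 3 (1 in box)
```

Reading the output: 11 of the 100 grid cells average two or more steady
states; the degree-2 fit wraps them in the ellipse `p(k) >= 1` (coefficients
above, in graded lexicographic order `1, k1, k2, k1², k1k2, k2²`), verified
to contain every selected cell. The monostationary point
`(k3, k8) = (0.0008, 0.25)` sits at Euclidean distance 0.75 from the fitted
boundary, the minimum over the Lagrangian critical points inside the box.

Other built-in systems: `quintic_fixture()` (a two-parameter degree-5
polynomial attaining 0–5 positive roots), `ssystem_fixture()` (a
non-rational S-system gene cascade whose steady states map to the positive
roots of a sparse degree-73 polynomial), `lacitetr_fixture()` (a
twelve-variable two-gene repression circuit, reduced by exact elimination),
and `synthetic_region_oracle()` (piecewise-constant counts with closed-form
expectations, for testing). The bisection searches
(`two_value_bisection()`, `two_step_bisection()`) build rectangular
decompositions adaptively from an expected-count oracle;
`workflow_end_to_end()` chains everything and a thin command-line wrapper
lives at `inst/cli/pss.R`.

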