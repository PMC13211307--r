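---
title: "Energetic feasibility domains: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetic feasibility domains: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enerfeas)
```

## The model and its assumptions

`enerfeas` studies communities of `S` populations with energy-based
Lotka–Volterra dynamics: population `i` captures mass-specific energy
`s_i >= 0` from the environment, pays a maintenance demand `d_i >= 0`,
and exchanges energy through `sigma` (units power·mass⁻²; the positive
diagonal is self-limitation). The energy densities `mu_i` only rescale
time, so they are stored but play no role in any feasibility
computation. Throughout, `sigma` is assumed **Volterra dissipative** —
its symmetric part is positive definite — which buys three things at
once: a unique, globally stable equilibrium for every capture vector,
a well-posed partition of capture space by equilibrium support, and
convexity of the maturation domain.

Interior equilibria solve `sigma N* = s - d`. For a candidate community
`C` (any subset of populations) the boundary equilibrium solves the
complementarity system `s - d = sum_{i in C} n_i sigma_i - sum_{i not
in C} n_i e_i`; members' multipliers are biomasses, non-members' are
invasion slacks, and the support is admissible exactly when all `S`
multipliers are positive. `classify_support()` finds the unique
admissible support by enumerating supports in decreasing cardinality
(at most `2^S` small solves, capped at `S <= 12`); multipliers within a
relative tolerance of `1e-9` of zero raise a tie error rather than
guessing a side.

## Domains and probabilities

Under a total supply `Q`, three nested convex bodies live in `s`-space:
the capture simplex `D_C` (volume `Q^S / (S! prod N0_i)` in closed
form), the initialization polytope `D_I` (the feasibility cone cut by
the simplex), and the maturation body `D_M` (`D_I` cut by the quadratic
`s'N*(s) <= Q`). Probabilities are volume ratios against `D_C`.

Strict inequalities (`s > 0`, `n_i > 0`) are stored as closed
constraints for volume purposes — boundaries carry no volume — with a
strictness flag used only by membership tests (absolute tolerance
`1e-12`). For partial communities the quadratic form in `s`-coordinates
need not be definite, so Monte Carlo volumes are computed in multiplier
coordinates, where the quadratic block is the principal submatrix
`sigma_CC` (positive-definite symmetric part under dissipativity) and
the Jacobian `|det B_C|` maps the volume back.

`Q_c`, the supply at which `D_I` first becomes nonempty, is the LP
infimum of `s'N0` over the closure of the feasibility cone. Since the
multiplier origin (`s = d`) is always feasible, `Q_c <= d'N0` exactly;
the implementation clamps away sub-1e-6 solver fuzz at the frequent
equality case. `Q_opt` is the grid argmax of the maturation curve,
refined by golden-section search on the exact quadrature probability
for two-population networks.

## The volume engine

**Exact polytope volumes.** Vertices are enumerated from the
H-representation by basis enumeration (every `d x d` subsystem of rows,
feasibility-checked; intended for `d <= 8`). The volume is decomposed
recursively: cones from an interior point over each facet, with facet
measures obtained by eliminating one coordinate against the facet
equality. Facets are deduplicated by their normalized rows and required
to have affine rank `d - 1`, which drops redundant and degenerate rows.

**Hit-and-Run.** The sampler (compiled, but seeded through R's RNG so
`set.seed()` controls everything) draws a uniform direction, intersects
the line with every half-space and with the quadratic (roots of a
scalar quadratic), and jumps uniformly on the chord. Default thinning
is `5 * d` chord steps per retained sample — a standard mixing
heuristic, exposed as an argument.

**Multiphase Monte Carlo.** Volumes of quadratically capped bodies use
the telescoping-ratio scheme: whiten the quadratic to a centered ball
via the Cholesky factor of its matrix (recording the log-Jacobian),
anchor at a ball of radius `r0` inside the body around an interior
point, grow radii by the schedule `r_i = r0 * 2^(i/d)` until a covering
radius, and estimate each ratio by sampling the larger intersection and
counting the smaller (the lower-variance direction). The covering
radius is the tighter of the quadratic's enclosing ball and a
coordinate bounding box from LPs, the latter inflated by 2% because the
LP layer is ridge-regularized — over-covering merely adds a cheap
phase, under-covering would bias the volume. The anchor uses
`anchor_shrink = 0.95` times the inscribed radius: the chain stays
strictly interior, and a body that *is* a ball still exercises one
genuine sampling phase instead of short-circuiting to the closed form.
Standard errors combine per-phase binomial variances by the delta
method; retained samples are treated as independent, which the `5 * d`
thinning makes a good approximation. Volumes below `1e-12` of the
capture simplex report as zero (floor flag) to keep downstream curve
analysis out of noise-dominated ratios.

**Independent routes.** Two cross-checks guard the stochastic path: an
exact 2-D quadrature (whiten, then clip the polygon against the disk —
machine precision, used by default for `S = 2`), and rejection sampling
from the capture simplex (exponential-spacings sampler) or a box. The
test suite requires all routes to agree within combined error on random
bodies, and the 12-dimensional unit ball to come out within 3% of
`pi^6/720` at the 1e5–1e6-sample budget.

**LPs.** Chebyshev centers, critical supplies and bounding boxes go
through `quadprog` with a tiny ridge (`~1e-9`, escalated on Cholesky
breakdown). A pure textbook simplex proved fragile on degenerate cone
polytopes; the regularized QP is always well-posed, and the `O(eps)`
objective perturbation is far below every tolerance used.

## Ensembles: what the generator emulates

`generate_network()` follows a four-step recipe: sample `sigma_ij ~
N(0,1)`; enforce transfer efficiency (for opposite-sign pairs, swap
absolute values so the negative entry is the smaller); shift the
diagonal so the symmetric part's minimum eigenvalue equals `sigma_0`;
scale by `s_sigma`. Step order is normative — flooring before scaling
makes the realized floor `sigma_0 * s_sigma`. Defaults are the study
conditions: `s_sigma = 1`, `sigma_0 = 0.5`, `N_0 = d_0 = 1`, full
connectance, with ensembles of size-8 networks down-sampled to smaller
sizes by taking leading principal submatrices (re-floored when the
submatrix dips below `sigma_0`, so every analyzed network is
dissipative). Two details the recipe leaves open are fixed here once:
the demand/biomass draws use sd `0.25 *` center with resampling of
non-positive values, and connectance masks off-diagonal *pairs*
together, keeping the pair semantics of the efficiency step coherent.

The generator emulates unstructured, statistically homogeneous
interaction networks. It does not emulate trophic hierarchy, degree
heterogeneity, correlated pair interactions, or empirically measured
food webs — so passing ensemble tests demonstrates the energetic
geometry on random dissipative networks, not on any particular natural
system. One distributional subtlety: the efficiency swap re-pairs
absolute values with signs, which slightly inflates the mean
off-diagonal entry (~+0.09 at `S = 8`) while preserving the second
moment exactly; the sanity test checks the preserved moment.

## Curves, FDA and diversity

Ensemble curves are evaluated by vectorized rejection classification:
uniform simplex samples are assigned to their unique support with one
small solve per support, which yields every community's initialization
and maturation probability from one sample set and makes the partition
sum to one by construction. The single-evaluation path
(`feasibility_probability()`) instead keeps `p_init` exact always and
`p_mat` exact whenever the quadratic is inactive at every polytope
vertex, falling back to quadrature (`S = 2`) or multiphase MC.

FDA follows the stated order: interpolate linearly in `(log Q, p)` onto
a common log-spaced grid (200 points by default; 500 matches the
published figures but triples runtime), clamp to `[1e-3, 1 - 1e-3]`,
logit, pointwise mean and sd (`n - 1`), inverse-logit the mean and the
±1 sd band. Extrapolation outside a curve's range is refused rather
than guessed. Diversity curves average on the original scale.

**Average diversity.** The default `average_diversity()` is the
maturation-mass-weighted sum `sum_C |C| p_mat(C)` over nonempty
communities. The normalized ratio (`/ sum_C p_mat(C)`) is available
behind a flag, but it saturates toward the largest community size at
high supply — the slowest-decaying size class dominates the ratio — and
therefore cannot peak at intermediate supply; the weighted sum is the
variant that exhibits the unimodal diversity–energy relationship, with
its peak below the full community's `Q_opt` (mid-sized communities are
combinatorially numerous and favored at intermediate windows). On a
seeded size-6 network the package computes a diversity peak near
`Q ≈ 13` against a full-community window near `Q ≈ 24`.

**Shape scores.** The saturation score (rank correlation times one
minus the normalized terminal slope) and unimodality score (one minus
the ratio of rise-then-fall to monotone isotonic residuals) are
package-defined plumbing for classifying curve shapes; they are
documented in `shape_scores()` and are not taken from any published
formula.

## Problem sizes and numerical choices

Validation runs at deliberately modest sizes chosen to exercise every
code path: exact volumes on dimensions 2–4 (hundreds of random bodies),
multiphase MC at 2e4 samples per phase for cross-checks and 2e5 for the
12-ball benchmark, ensembles of 20 replicates at `S ∈ {2, 4}` on
100-point grids, and a 40-point grid with 2e4 classification samples
per point for the size-6 partition analysis (its per-size argmax is
taken after a fixed 3-point moving average to damp Monte Carlo noise).
Ties, degenerate supports, empty bodies and lower-dimensional polytopes
all resolve to explicit flags or zero volumes rather than exceptions in
volume paths; membership tolerances are `1e-10`–`1e-12` absolute.

## Known limitations

Only equilibria matter here: no trajectory integration, no non-point
attractors, no assembly/disassembly dynamics across partition
boundaries, and no mechanistic map from supply `Q` to realized capture
rates `s`. Density-dependent (saturating) capture kinetics are out of
scope. Exact polytope volumes are practical to `S ≈ 8`; beyond that the
stochastic routes are the only option, and support enumeration is
capped at `S = 12`. Positive biomass thresholds `eps_i > 0` (instead of
`N* > 0`) would shift the cone constraints affinely; the machinery
accepts only `eps = 0` and deliberately flags rather than extrapolates
the general case.
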