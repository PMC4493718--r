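---
title: "Crowding-constrained flux sampling and the two-cell lactate shuttle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding-constrained flux sampling and the two-cell lactate shuttle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdflux)
```

## The model

A cell at metabolic steady state routes a glucose supply $U_G$ through a
glycolytic flux $f_{glyc}$ (2 ATP and 2 pyruvate per glucose), an OXPHOS flux
$f_{ox}$ (18 ATP per pyruvate) and an LDH flux $f_{LDH}$ (pyruvate to
lactate, no ATP). Mass balance of pyruvate forces
$f_{ox} + f_{LDH} = 2 f_{glyc}$, and ATP output is
$f_{ATP} = 2 f_{glyc} + 18 f_{ox}$, so the best possible yield is 38 ATP per
glucose. The distinguishing constraint is *macromolecular crowding*: the
enzymes of the three routes compete for a finite volume (equivalently,
proteome) budget,
$$a_{glyc} f_{glyc} + a_{ox} f_{ox} + a_{LDH} |f_{LDH}| \le \Phi_{ATP},$$
with empirical coefficients $a_{glyc} = 3\times 10^{-3}$,
$a_{LDH} = 4.6\times 10^{-4}$, $a_{ox} = 2\times 10^{-1}$ min/mM and budget
$\Phi_{ATP} = 0.4$. Because OXPHOS is by far the most volume-hungry route per
unit flux, ATP-maximizing cells are fully oxidative only up to the crowding
onset $u_G = \Phi_{ATP}/(2a_{ox} + a_{glyc}) \approx 0.99$ mM/min; beyond it
they divert the surplus to LDH and secrete lactate (aerobic glycolysis), and
at $v_G = \Phi_{ATP}/(2a_{LDH} + a_{glyc}) \approx 102$ mM/min glucose is
entirely fermented — no single cell can process more. `thresholds()` returns
these numbers; `single_cell_optimum()` returns the piecewise closed form.

### Two cells, one glucose pool

`two_cell_solution()` couples two such cells sharing the supply: a *donor*
that maximizes its ATP production and can only secrete lactate, and an
*acceptor* that must make at least a survival flux $f_{ATP,min}$ and can also
import lactate, reconverting it to pyruvate through reverse LDH. Four regimes
arise as the total supply grows: starvation (infeasible below $2u_{G,0}$ with
$u_{G,0} = f_{ATP,min}/38$), glucose sharing, a lactate-subsidized band
$(u_{G,1}, u_{G,2}]$ in which the donor reroutes up to $u_{G,0}$ of the
acceptor's glucose and pays it back in lactate, and full sequestration, where
the acceptor's state is no longer unique and the package reports its feasible
range (computed exactly by vertex enumeration of the acceptor's
two-dimensional polygon in glucose-intake/LDH coordinates).

`lp_oracle()` re-derives all of this by brute force: the six-flux linear
program is solved by a generic simplex routine and the acceptor range by
min/max subproblems at the pinned donor optimum. The closed forms and the
oracle agree to better than $10^{-6}$ across all regimes (this is itself a
test), which is the package's guard against algebra slips: the piecewise
solution was derived from the stated constraints rather than transcribed.

### A degenerate optimum worth knowing about

One non-obvious feature falls out of the algebra: wherever the pair is
glucose-limited, feeding the acceptor one unit of glucose costs the donor
exactly the 38 ATP the acceptor gains, and feeding it lactate costs 18 ATP
per lactate — also exactly the acceptor's gain. Donor-optimal states
therefore form a *segment* ($f_{ATP,don} = 38 U_G - f_{ATP,min}$ on all of
it), stretching from "share the glucose" to "sequester everything and shuttle
lactate", as far as the donor's own crowding budget allows. The closed-form
solution reported by `two_cell_solution()` is the minimal-donor-glucose
endpoint of that segment (the autonomous-maximizer convention, which the LP
oracle enforces by a lexicographic tie-break); a Boltzmann sampler at large
$\beta$ instead equilibrates over the whole optimal face, so its *mean* shows
the donor sequestering nearly all glucose and leaking lactate even below the
overflow threshold. Both descriptions are correct; tests compare sampled
means against the face (its value, its range, and flux conservation across
the shuttle), not against the endpoint.

### The survival bound

The survival flux defaults to $f_{ATP,min} = 1\,u_G$ (an ATP flux numerically
equal to the crowding-onset glucose flux), so $u_{G,0} = u_G/38$. The package
deliberately does not default to $u_{G,0} = u_G$: lactate-derived ATP costs
$(a_{ox}+a_{LDH})/18 \approx 1.11\times 10^{-2}$ of volume per ATP versus
$(a_{glyc}+2a_{ox})/38 \approx 1.06\times 10^{-2}$ for glucose-derived ATP,
so an acceptor that already saturates its crowding budget at survival can
never substitute lactate for glucose — the subsidized band would be empty.
Any `f_atp_min` may be supplied; the constructor and the two-cell solver
check the geometry and fail loudly rather than return an inconsistent
regime structure.

## Large networks

For a general stoichiometric network (`metabolic_network()`, read from the
tabular dialect or SBML) the same analysis is done by sampling instead of
algebra:

1. **Reduction** (`flux_polytope()`): Gauss–Jordan elimination brings $S$ to
   reduced row echelon form, splitting fluxes into dependent and free ones;
   the steady-state set becomes a polytope of dimension
   $D = N - \mathrm{rank}(S)$ over the free fluxes. Elimination is done in
   floating point with a $10^{-9}$ pivot tolerance and a fixed column order,
   which keeps the pivot/free split deterministic and reproducible; the
   dimension is cross-checked against a singular-value rank oracle in the
   tests. The minimal cell reduces to $D = 2$, its coupled pair to $D = 4$.
2. **Interior point** (`find_interior_point()`): a Chebyshev-center linear
   program, with an iterative most-violated-constraint relaxation as
   fallback; empty-interior (degenerate) and infeasible polytopes raise
   distinct errors.
3. **Rounding** (`round_polytope()`): three rounds of covariance estimation
   from short uniform chains. Flux polytopes are extremely anisotropic (the
   bundled box fixture has an axis ratio of $10^4$, comparable to realistic
   networks); drawing Hit-and-Run directions isotropically under the
   estimated covariance metric removes the ill-conditioning, cutting the
   slow-mode autocorrelation time by an order of magnitude or more.
4. **Sampling** (`hit_and_run()`): from the current point, draw a direction
   (normalized standard-normal vector mapped through the metric's Cholesky
   factor), intersect the line with the polytope (`chord()`), and draw the
   next point from the density $\propto e^{\beta\,s\,t}$ on the chord, where
   $s$ is the exact directional slope of the linear objective obtained
   through the affine map (no finite differences). $\beta = 0$ is uniform
   sampling; large $\beta$ concentrates on objective maximizers. The
   inverse-CDF draw is formulated in the log domain and is stable for
   $|\beta s (t_{max}-t_{min})|$ up to $\sim 10^3$.

Crowding enters as extra inequality rows (`crowding_rows()`): coefficients
attach to the hexokinase, PDH, LDH and (optionally) glutaminase roles, and a
reversible LDH contributes $|f_{LDH}|$, encoded exactly as two rows.
Glutaminase has no published coefficient of its own and shares the PDH value
by default (both are mitochondrial volume-occupying fluxes); this is
configurable. Two-cell coupling (`couple_cells()`) replicates the network,
clamps the donor's lactate exchange to secretion, opens the acceptor's, and
adds the two shared rows $U_{G,don} + U_{G,acc} \le U_G$ and
$U_{LAC,don} + U_{LAC,acc} \ge 0$ (no external lactate source). A
`symmetric` flag keeps both exchanges reversible for control experiments.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `a_glyc`, `a_ldh`, `a_ox` | 3e-3, 4.6e-4, 2e-1 | min/mM | empirical volume-per-flux estimates of the coarse-grained model |
| `phi_atp` | 0.4 | — | volume fraction available to ATP production |
| `f_atp_min` | $1 u_G$ | mM/min | survival ATP flux (see above) |
| `beta` | 0 | — | bias strength; ~50 suffices to reach the optimum on the fixtures |
| `burn_in` | $10 D^2$ | steps | conservative multiple of the $O(D^2)$ post-rounding mixing time |
| `thinning` | $D$ | steps | decorrelation between retained samples |
| `fmax` | $10^4$ | flux | finite cap replacing unbounded exchanges (e.g. oxygen); flagged when applied |
| rounding rounds | 3 | — | covariance estimate converges on the fixtures in 2 |
| retry cap | 100 | — | degenerate-chord retries near thin facets |

Numerical conventions: mass-balance residuals and crowding slacks are
checked at $10^{-8}$ (`validate_flux()`); the oracle pins optima with a
$10^{-9}$-scaled tolerance because exact-equality pinning of an LP optimum
is knife-edge infeasible in floating point; zero-variance fluxes get Pearson
$r = 0$ with a flag (correlating a constraint-pinned flux is meaningless);
scan standard errors use batch means over 20 batches because the chain is
serially correlated.

## What the fixtures emulate — and what they do not

The bundled fixtures (`fixture()`, `make_fixture()`) are built in code, not
shipped as data. `minimal-single` and `minimal-two-cell` reproduce the
coarse-grained stoichiometry exactly (glucose $\to$ 2 pyruvate + 2 ATP;
pyruvate $\to$ 18 ATP; pyruvate $\leftrightarrow$ lactate), so every sampler
result can be checked against closed forms; `triangle-toy` and
`anisotropic-box` have analytic uniform marginals (Beta(1,2)) and a known
$10^4$ axis ratio for sampler and rounding validation. They deliberately do
*not* emulate features of genome-scale reconstructions: no pentose-phosphate
or TCA detail, no cofactor bookkeeping beyond ATP, no thermodynamic loop
structure, and only $\sim$2 effective degrees of freedom per cell. Passing
tests on the fixtures therefore demonstrate correctness of the machinery and
of the coarse-grained theory, not biological completeness; with a deposited
large network supplied as SBML, the same pipeline reports its parsed counts,
reduction dimensions and yield curves (an opt-in test covers the published
67-species/75-reaction core catabolic network when its file is provided).

One fixture-size effect is worth flagging for correlation analyses: with
$D = 4$, the shared-glucose facet pins both cells to essentially one
fluctuating degree of freedom whenever glucose is limiting, so donor-acceptor
cross-correlations are already near-maximal below the overflow threshold and
the rise into the subsidized band is small (on a large network, internal
fluxes dilute the low-supply block). The robust fixture signatures are the
strong negative lactate-lactate correlation while the shuttle runs and the
collapse of all cross-correlations once $U_G \ge 2 v_G$.

## Problem sizes

The shipped tests and the acceptance script run chains of $10^3$–$2\times
10^4$ retained samples on polytopes of dimension 2–4, which resolves means
to $\sim$0.1% and keeps the whole suite in the minutes range on one core;
the same code paths apply unchanged to larger networks, where rounding
dominates preprocessing and chain length should grow with $D^2$.

## Known limitations

- Steady states only; no kinetics, no dynamics, at most two coupled cells.
- The simplex subroutine is dense and suited to the small programs used
  here; genome-scale FBA-style LPs would want a sparse solver.
- RREF is floating-point (tolerance-pivoted), not exact-rational; stoich
  matrices with pathological conditioning could mis-rank, which the rank
  oracle in the tests would catch for the shipped networks.
- At very large $\beta$ the chain mixes slowly *along* the optimal face
  (the rounding metric is fitted to the $\beta = 0$ body); prefer moderate
  $\beta$ with longer burn-in when means over a degenerate optimum matter.
- Biomass-style objectives are supported as arbitrary named coefficient
  vectors; no curated biomass composition ships with the package.
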