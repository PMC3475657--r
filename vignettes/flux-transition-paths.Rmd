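---
title: "Probability fluxes and transition paths in ladder models of ligand-gated gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability fluxes and transition paths in ladder models of ligand-gated gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatingflux)
```

## The model

Ligand-gated channels such as HCN2 are tetramers with one cyclic-nucleotide
binding site per subunit. Their gating is commonly described by a
*ladder-type* Markov scheme: a row of closed states `C0 … Cn` and a row of
open states `O0 … On`, indexed by the number of bound ligands, with a
closed–open isomerization at every liganding level. With `n = 4` binding
steps this is the ten-state C4L–O4L scheme with 13 reversible transitions
(4 closed-row binding steps, 4 open-row binding steps, 5 isomerizations).

The occupancy vector `P(t)` obeys the master equation `dP/dt = Q(L) P`,
where we use the **column-generator convention**: the off-diagonal entry
`Q[Y, X]` is the rate constant of `X → Y`, binding (association) rates are
stored at unit concentration in 1/(µM·s) and multiplied by the ligand
concentration `L` only when the generator is assembled, and every column of
`Q` sums to zero. All modules of the package share this convention.

Every square of the ladder, `C(x−1)–Cx–Ox–O(x−1)`, is a reaction cycle. A
physically consistent (thermodynamically reversible) model satisfies
detailed balance on each square: the product of rate constants clockwise
equals the product counter-clockwise (the concentration factors cancel, one
binding step in each direction). `build_ladder_model()` rejects models whose
relative cycle residual exceeds `1e-6`; the tolerance is deliberately loose
enough to accept rate tables rounded to two significant figures, while
`detailed_balance_residuals()` reports the raw residuals (a zero rate in
the counter-clockwise product is reported as an infinite residual rather
than an error).

## Concentration-jump relaxations

The experiment the package emulates is a concentration jump: the channel
equilibrates at `L = 0`, the ligand is stepped to a pulse concentration
(7.5 µM saturates the binding steps of this scheme; 0.75 µM and 0.075 µM
are the sub-saturating presets) for 5 s, then removed for 20 s. Jumps are
treated as instantaneous: solution exchange kinetics are not modelled, so
occupancies are continuous across a jump while the rates switch.

At `L = 0` the generator is reducible — liganded states can drain but never
refill — so the pre-pulse equilibrium is defined on the unliganded pair
alone: `P(C0) : P(O0) = k_close : k_open`, zero elsewhere. This matches the
physical initial condition of a ligand-free patch.

`propagate()` solves the master equation by eigen-decomposition. Because a
detailed-balance generator is similar to a symmetric matrix through the
stationary-distribution transform `S = D^{-1/2} Q D^{1/2}` with
`D = diag(π)`, the spectrum is real and the symmetric eigenproblem is
numerically robust; the package uses this route whenever every stationary
weight is positive. At `L = 0` (zero stationary weight on liganded states)
it falls back to a general eigen-decomposition, and — should that ever be
ill-conditioned (reciprocal condition number of the eigenvector matrix
below `1e-10`) — to a scaled-and-squared matrix exponential with a warning.
In the fallback case no spectral data are stored and downstream integrals
use Simpson quadrature instead of the exact spectral form.

The default time grid has 2001 points per segment: half geometric from
`0.01 · t_end/(n−1)` to `t_end/10`, half uniform beyond, plus `t = 0`. Flux
densities peak within the first tens of milliseconds after a jump, so the
geometric part resolves the fast transient while the uniform part covers
the slow tail; the smallest step scales with `1/n` so that quadrature on
the grid converges under refinement, and the odd point count lets composite
Simpson integration consume the grid in interval pairs.

## Flux densities and total fluxes

For a transition `X → Y` with forward (binding/opening) rate `k_f` and
backward rate `k_b`, the unidirectional probability flux densities are
`f_fwd(t) = k_f(L) P_X(t) ≥ 0` and `f_bwd(t) = −k_b P_Y(t) ≤ 0`, and the
net density is their sum `f(t) = k_f(L) P_X − k_b P_Y`, positive in the
binding/opening direction. At equilibrium every net density vanishes while
the opposed unidirectional components may remain large — the kinetic
signature of conformational flexibility across that transition; small
opposed components indicate a taut conformation.

The total net flux of an edge is the time integral of its net density from
the jump to `t_end` (5 s for the pulse, 20 s for the wash by default), a
signed dimensionless probability. Two quadratures are provided:

* `"spectral"` (default): since `P(t) = A exp(λt)` on each segment, the
  integral is exact — each mode contributes `(e^{λ t_end} − 1)/λ`, the
  conserved `λ = 0` mode contributes `t_end`.
* `"simpson"`: composite Simpson coefficients on the stored grid (a
  quadratic through each interval pair, valid on non-uniform spacing);
  retained for trajectories that carry no spectral data and as an
  independent numerical cross-check.

Signed totals are preserved (deactivation totals are negative); nothing is
folded into magnitudes, so activation and deactivation bar patterns can be
compared directly.

`flux_divergence_check()` audits the results: for every state, integrated
inflow minus outflow must equal its occupancy change (Kirchhoff's rule with
storage). With spectral integration the residuals sit at numerical
round-off (`~1e-13`); the test suite requires `< 1e-6`.

## Transition-path decomposition

Over a relaxation each state is a flux **producer** (occupancy decreases),
a **collector** (occupancy increases) or pass-through. The classification
threshold defaults to `|ΔP| > 1e-4`; it only labels states for reporting.
The decomposition itself uses each node's *exact* divergence so that no
flux is lost to thresholding.

The integrated fluxes, oriented along their sign and weighted by
magnitude, form a directed graph. For a detailed-balance model this graph
is acyclic; residual cycles can only arise from numerical noise and are
cancelled by subtracting their bottleneck (a cycle carrying more than
`1e-3` of the largest edge weight is an error, as it indicates a genuine
reversibility violation).

The graph is then decomposed into ranked source→sink pathway fluxes:
repeatedly extract the *strongest* remaining pathway, assign it the
minimum available flux along it, subtract that weight from its edges, and
continue until nothing above tolerance (`1e-12`) remains. Two design
choices deserve explanation:

* **"Strongest" is formalized as the widest (maximum-bottleneck) path**,
  computed by max–min dynamic programming in topological order. Ties are
  broken deterministically: fewest edges first, then the lexicographically
  smallest state sequence — found exactly by restricting to edges at least
  as wide as the optimum and taking the lexicographically smallest
  shortest path in that subgraph.
* **Endpoint capacities are part of the bottleneck.** A naive "any
  producer to any collector" extraction can drain a wide path into a
  collector that only absorbs a sliver of it, leaving flux that no later
  path can account for. The package therefore augments the graph with a
  virtual super-source feeding each node of negative divergence (capacity
  = its deficit) and a virtual super-sink draining each node of positive
  divergence. The extraction then is a standard flow decomposition: on a
  conserved flux graph the per-edge sums of pathway weights reproduce the
  original edge weights to round-off, and the total decomposed equals the
  total produced.

Like any flow decomposition the individual pathway weights are not unique
— a different extraction order redistributes weight among overlapping
paths — but per-edge sums are invariant. The test suite asserts this by
replaying the extraction with a second, lexicographic order.

Hysteresis is quantified from the closed–open crossings: for each
isomerization edge, the summed weight of pathways crossing it is tabulated
for activation and deactivation, and the **hysteresis index** is the total
variation distance between the two normalized crossing distributions (0 =
identical usage, 1 = disjoint edges).

## The synthetic generator and the demo model

The experimentally fitted rate table behind the published C4L–O4L analysis
is not reproduced in text form, so the package ships a generator and a
synthetic demonstration model instead; both are first-class, tested code.

`generate_ladder_rates()` samples closed-row binding and all isomerization
rates log-uniformly (defaults: association 0.1–10 µM⁻¹s⁻¹, approaching the
diffusion limit at the top; dissociation 0.1–20 s⁻¹; isomerization
0.1–200 s⁻¹, spanning slow gating to fast flicker), samples each open-row
association rate, and *solves* the open-row dissociation rate from the
square-cycle balance condition — so every generated model satisfies
detailed balance exactly, by construction. Pinned rates (e.g. the two
published constraints) override sampled values before closure; pinning a
balance-closed rate inconsistently is an error naming the cycle.

`demo_ladder_model()` is hand-tuned rather than sampled. It pins the two
published constraints `k_O3C3 = k_O4C4 = 3 s⁻¹`,
`k_C3O3 = k_C4O4 = 2.0×10² s⁻¹` and chooses the other eleven transitions
to reproduce the qualitative gating phenotype: a mostly closed ligand-free
equilibrium (`K_iso(0) = 1/6`), a strongly opening singly liganded channel,
a taut doubly liganded channel (both `C2O2` rates small, so the opening
flux through `x = 2` is negligible), fast unbinding at the top of the open
row with a metastable `O2`, and slow escape from `O1`/`O0`. Under the
default protocol this yields activation entering the open row mainly at
one, three and four ligands, deactivation leaving it at two, one and zero,
and a hysteresis index of 0.62. The demo is synthetic: its free rates make
no claim of equalling the experimental fit, and analyses of it demonstrate
the machinery, not the biology of HCN2.

## The stochastic oracle

Every deterministic quantity is cross-validated against an exact
stochastic simulation (`gillespie_ensemble()`, compiled core): independent
channels, per-channel RNG streams derived from one root seed (so results
are reproducible and order-independent), rates switching at the protocol
jumps. Occupancy is sampled at bin edges; directed transition events are
counted per bin, giving empirical unidirectional flux densities
`counts/(N · Δt)` with Poisson errors. The agreement criterion used in the
tests is 3 standard errors at ≥ 99 % of checked points with `N = 10⁵`
channels — the binomial/Poisson tail plus the small bias of comparing a
bin average against a trapezoidal midpoint leaves about half a percent of
points outside.

The ensemble emulates ideal, independent, identical channels. It shares
every modelling idealization of the deterministic pipeline (instantaneous
jumps, concentration-independent rates, no photophysics or measurement
noise), so agreement between the two routes validates the numerics, not
the biological realism of the model.

## Problem sizes and tolerances used in the tests

The suite runs 50 random ladders (1–4 steps) through the full protocol for
the conservation checks (probability conserved to `1e-9`, divergence audit
to `1e-6`), 20 ladders against an adaptive ODE oracle (`1e-6`), 100 random
conserved-flux DAGs of up to 10 nodes for the decomposition invariants
(`1e-9`), and one `10⁵`-channel ensemble of the demo model for the
stochastic comparison. The demo's hysteresis index is frozen in the tests
as a regression value (`0.6213947…`); it characterizes the shipped
configuration, not the published channel.

## Known limitations

* Rates are treated as voltage-independent constants (the emulated
  experiments hold the membrane at a fixed activating voltage).
* Ionic currents are not computed; the analysis is purely probabilistic
  (no conductance weighting of open states).
* The pathway decomposition operates on time-integrated relaxation fluxes
  between equilibria; committor-based transition-path formulations for
  stationary processes are out of scope.
* Pathway weights beyond the per-edge sums are extraction-order dependent;
  compare decompositions only together with the documented tie-break.
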