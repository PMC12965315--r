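---
title: "Cooperation thresholds for public goods games on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperation thresholds for public goods games on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggnet)
```

## The model

A population of `N` agents occupies the nodes of a simple, connected,
unweighted network. Agent `i` has `k_i` neighbours and organises a group
`G_i` consisting of itself and its neighbours, of size `G_i = k_i + 1`. A
public goods game (PGG) is played in every group: each cooperating member
contributes a cost `c` to the pool, the pool is multiplied by the synergy
factor `r` and divided equally among the `G` members. A member therefore
receives `r c g_C / G` from a group containing `g_C` cooperators, minus `c`
if it contributed itself. Because every agent belongs to `G_i` groups (its
own and one per neighbour), its *actual payoff* `f_i` is the average of its
`G_i` per-game payoffs — or their sum, under the accumulated-payoff
variant. Defectors always earn more than cooperators within any one group;
whether cooperation can nevertheless spread is a population-dynamics
question, and the answer depends on the network.

Strategies evolve by one of three standard update rules, applied once per
elementary step to a single node (one full Monte Carlo step is `N`
elementary steps):

* **PC** (pairwise comparison): a uniform focal agent `i` picks a uniform
  neighbour `j` and adopts `j`'s strategy with the Fermi probability
  `1 / (1 + exp(-delta (f_j - f_i)))`.
* **DB** (death-birth): a uniform agent dies; its neighbours compete for
  the vacancy proportionally to fitness `F = exp(delta f)`.
* **BD** (birth-death): an agent is chosen proportionally to fitness in
  the whole population; its strategy replaces a uniform neighbour.

`delta` is the selection strength; the theory below is exact in the
weak-selection limit `delta -> 0`, where the dynamics is a small
perturbation of neutral drift. Cooperation is *favoured* when a single
cooperator placed at a uniformly random node fixates with probability
above the neutral benchmark `1/N`. The package computes the critical
synergy factor `r*` above which this happens, and the analogous critical
benefit-to-cost ratio `(b/c)*` for the pairwise donation game (DG), in
which a cooperator pays `c` per neighbour to deliver `b`.

## The weak-selection theory

Under neutral drift the strategy process is a voter model, and its
two-point correlations are governed by *coalescing ancestral random
walks*: tracing who copied whom backwards in time, the lineages of two
nodes perform random walks that merge when they meet. For the PC and DB
rules the expected meeting times `tau_ij` solve

    tau_ij = 1 + (1/(2 k_i)) sum_{l in N_i} tau_lj
               + (1/(2 k_j)) sum_{l in N_j} tau_il,    tau_ii = 0,

i.e. each of the two walkers moves with probability 1/2 per time unit
(`solve_coalescence_times()`). Under BD a node is replaced at a rate
proportional to its temperature `T_i = sum_{g in N_i} 1/k_g` and copies a
neighbour `g` with weight `1/k_g`, so the BD ancestral process is a
different coalescing walk with its own meeting-time system
(`bd_meeting_times()`). This is why the BD conditions use their own
times: the backward dynamics, not just the forward weights, differ.

Writing the payoffs as a linear map `f = c (r B x - D x)` of the 0/1
strategy vector `x` (the coefficients `B`, `D` encode the group structure
and payoff scheme), a first-order perturbation of the fixation
probability in `delta` gives the cooperation condition

    sum_{i,j,l} W_ij (a_il - a_jl) (tau_jl - tau_il)  >  0,

with rule-specific pair weights `W_ij`: `k_ij` (PC), `k_i p2_ij` (DB,
with `p2` the two-step walk kernel — DB competition reaches second
neighbours), and `k_ij / (k_i k_j)` (BD). The condition is linear in `r`,
so the threshold is a ratio of a cost sum to a benefit sum. Under PC with
average payoffs it reduces to the compact form `tau(1)/Upsilon(1)`, and
under DB to `tau(2)/Upsilon(2)`, where `tau(n)` and `Upsilon(n)` weight
the coalescence times and the payoff-aggregated matrix `Upsilon`
(`upsilon_matrix()`) by `k_i p^(n)_ij`. The same machinery covers
accumulated payoffs (coefficients scaled by group size) and the donation
game (for which the DB average-payoff threshold is the classic
`tau2 / (tau3 - tau1)` of pairwise-game theory).

Three structural facts drive the results. First, group separation gives
PGGs a self-reciprocity channel: a cooperator's contribution partly
returns to itself, which no pairwise game offers. Second, a *negative*
benefit sum flips the inequality: the condition becomes `r < r* < 0` and
cooperation is impossible at any sensible `r`; a vanishing benefit sum
means the threshold diverges. Thresholds are therefore reported with a
category: `finite_supporting` (`0 < r* <= 30`), `strict`
(`30 < r* <= 1000`) and `no_support` (negative, or above the numerical
infinity proxy 1000). Third, on the complete graph all groups coincide,
group separation vanishes, and the PGG supports no cooperation at any
`r` — the benefit sum is exactly zero there.

```{r star}
pgg_critical_r(make_star(9), "db")     # the star: r* = 4 at every size
dg_critical_bc(make_star(9), "db")     # the pairwise game fails on the star
```

## Validation: an exact oracle

Every formula above is cross-checked against a brute-force computation
that shares nothing with it: `exact_fixation_probability()` builds the
full `2^N`-state Markov chain of the dynamics at finite `delta`, solves
the absorbing-chain system, and `oracle_critical()` recovers the critical
factor from the finite-difference derivative at `delta = 0` (step `1e-4`,
refined at `5e-5` when the two estimates disagree by more than `1e-5`
relative; the derivative is linear in `r` to machine precision, which the
tests verify by three-point collinearity). The test suite runs this
comparison over *all* 141 connected graphs with up to six nodes, all
three rules and both games at relative tolerance `1e-4`. The oracle is
also how the BD condition and the accumulated-payoff variants were
gated during development: any mis-derivation of the pair weights or
meeting-time system fails hundreds of graph-by-graph comparisons at once.

## Synthetic families and the graph census

Generators are provided for the deterministic families (stars, joint
stars, ceiling fans, periodic von Neumann and Moore lattices) and the
random ones (Erdős–Rényi, Watts–Strogatz, Krapivsky-style preferential
attachment with tunable exponent `gamma`). Known limits recovered by the
package: the star's DB threshold is exactly 4 at every size; ceiling fans
tend to 21/4 (PC) and 27/8 (DB); joint stars with `m` hubs tend to
`4m/(2m-1)` (PC) and `(12m-4)/(9m-7)` (DB); the Moore lattice under DB
tends to about 5.79. Infinite-size values are obtained by computing the
threshold along a ladder of sizes and fitting `a + b/n`
(`extrapolate_threshold()`); `1/n` is the observed leading order, and the
fit residual is reported so a bad extrapolation is visible. The ladders
used in the tests and the acceptance script (fan counts up to 80, lattice
sides up to 20, leaf counts up to 200) keep each extrapolation within a
few hundredths of its limit at desk-scale cost.

`enumerate_connected()` generates every connected graph on 3–8 nodes up
to isomorphism (2, 6, 21, 112, 853, 11,117 classes) by canonical
augmentation: every connected graph on `n` nodes arises by attaching a
new node to a non-empty subset of a connected graph on `n - 1` nodes, and
duplicates are pruned with BLISS canonical labelling. `census_thresholds()`
then solves each graph's coalescence systems once and evaluates all
requested rule × game combinations, so the full 12,111-graph census with
six combinations runs in about a minute. Nearly 99% of all these networks
support cooperation in the PGG with `r* <= 30` under every rule, the
*only* failures being the six complete graphs; the donation game fails on
every network under PC and BD and on half of them under DB. Rankings
within a size class sort by threshold value with `no_support` last; ties
(rare) share the minimal rank.

## The simulator and what it can show

`estimate_cooperation()` runs the exact stochastic dynamics (compiled
inner loop; xoshiro256++ streams derived from a master seed and the run
index, so results are bit-reproducible and order-independent) from a
single random cooperator, to fixation or a 4×10^5-MCS truncation, and
averages the final cooperator fraction over independent runs.

Design of the simulation consistency check: at numerically weak selection
the deviation of the mean from `1/N` is `delta * slope * (r - r*)` to
first order, which for the 10-node star is about `2e-3` at `delta =
0.025` and `r = 8` — comparable to the standard error of `1e5` runs at a
single point. A single far-off point is therefore underpowered, and the
check instead fits the mean against a grid of `r` values (1–10 for the
star, 2–8 for the 5×5 lattice, `1e5` runs per point) by weighted least
squares, treating the per-point standard errors as known variances, and
brackets the crossing of `1/N` with a Fieller 95% interval
(`estimate_crossing()`). `delta = 0.025` sits at the weak end of the
customary range and maximises signal without leaving the linear regime
(the exact oracle puts the second-order deviation at about 1% of the
first-order term there). The truncation cap is effectively never hit on
these small graphs — runs fixate within a few thousand elementary steps.

What the simulator emulates is exactly the model: asynchronous
elementary updates, exponential fitness, one initial cooperator. What it
does *not* emulate is anything beyond the model — no mutation, no noise
in the payoff structure, no dynamic rewiring — so agreement between
simulation and theory validates the derivation, not the model's fit to
any empirical system. Likewise the random-network generators reproduce
the stated sampling models (conditioned on connectivity by whole-graph
rejection); real networks have degree correlations, communities and
weighted ties that none of these families capture, and thresholds for an
empirical system should be computed on its own edge list (read with
`read_edge_list()`) rather than extrapolated from a synthetic family.

## Numerical choices and conventions

* **Pair-system solver.** The coalescence equations over `N(N-1)/2`
  unordered pairs are solved directly below 3000 unknowns. Larger systems
  are symmetrised exactly — scaling the `(i,j)` equation by `k_i k_j`
  (by `1/(k_i k_j)` for the BD system) yields a symmetric positive
  definite M-matrix — and solved by Jacobi-preconditioned conjugate
  gradient to a relative residual of `1e-12` (a few dozen iterations even
  at `N = 400`; sparse triangular factorisations of these torus-like pair
  graphs fill in catastrophically, which is why an iterative method is
  used).
* **Degenerate ratios.** If the benefit sum is below `1e-12` times the
  cost sum in magnitude the threshold is reported as infinite
  (`no_support`): the ratio is meaningless below solver precision.
  The category boundaries 30 and 1000 follow the numerical convention of
  treating values above 1000 as divergent.
* **Small populations.** Thresholds require `N >= 3`: with two nodes the
  group games collapse onto a single shared pair and the PGG and DG
  coincide up to scaling. The oracle accepts `N = 2` (useful for
  neutrality checks) but the threshold functions reject it.
* **Connectivity of random draws.** ER and WS graphs are resampled whole
  until connected (at most 10,000 attempts), preserving the conditional
  distribution; for very sparse parameters this conditioning is the
  dominant feature of the ensemble.
* **Preferential attachment at degree zero.** The attachment weight
  `k^gamma` is undefined for the isolated initial nodes; they are given
  unit weight. This minimal convention only matters for the first few
  attachments, and none of the package's quantitative claims depend on
  it. With isolated initial nodes the edge count is exactly
  `m (N - m)`, giving mean degree `2m(1 - m/N)`.
* **Watts–Strogatz procedure.** Each node considers its `d` clockwise
  original edges once, in index order, and rewires the far endpoint with
  probability `p` to a uniformly chosen non-neighbour; an edge is never
  rewired twice, and the edge count is invariant.
* **Ranking ties.** Graphs with equal thresholds (to `1e-9`) share the
  minimal rank; `no_support` graphs rank after all finite thresholds.
* **Accumulated-payoff limits.** The joined-star accumulated-DB threshold
  is treated as a large-`n` limit and obtained by extrapolation; at
  finite `n` the computed values are visibly above 1.

## Limitations

The theory is exact only to first order in `delta`; at strong selection
the thresholds are qualitative guides, and the package deliberately does
not expose a strong-selection mode. Weighted, directed, dynamic and
multilayer networks are out of scope, as are nonlinear public goods and
initial conditions other than a single invading cooperator. Exhaustive
enumeration stops at `N = 8` (the next class, `N = 9`, has over 260,000
graphs), and the exact oracle at `N = 12` by memory; the threshold
computation itself is polynomial and comfortably handles hundreds of
nodes.
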