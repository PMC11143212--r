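---
title: "Methods: degree-class theory of fixation on graphs and the spatial niche pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degree-class theory of fixation on graphs and the spatial niche pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evograph)
```

## The model

A population of `N` haploid individuals occupies the nodes of a simple,
undirected, connected graph. Edges are the local pattern of replacement:
an offspring can only take over a node adjacent to its parent. One mutant
with relative fitness `1 + s` (wild type 1) appears at a node at time zero;
there is no further mutation, so the chain is absorbed at all-mutant
(fixation) or all-wild-type (loss). Two update rules are supported:

* **Bd (Birth-death)** — a reproducer is drawn from the whole population
  with probability proportional to fitness, then one of its neighbours is
  drawn uniformly to die and is replaced by the offspring. Competition is
  global, replacement local.
* **dB (death-Birth)** — a node is drawn uniformly to be vacated, then one of
  its neighbours reproduces into it with probability proportional to
  fitness. Space frees up first, competition is local.

The well-mixed benchmark is the complete graph, where the fixation
probability has the classical birth-death-chain form
`rho = (1 - (1+s)^-1) / (1 - (1+s)^-N)` with neutral limit `1/N`
(`wellmixed_baseline()`). A structure whose fixation probability exceeds
this benchmark amplifies selection; one below it suppresses selection.

## Degree-class reduction and the diffusion approximation

Tracking all `2^N` occupancy states is exact but exponential
(`exact_fixation()` does it, and is deliberately capped at `N <= 14`; it is
the package's oracle, not its workhorse). The scalable approximation keeps
only the mutant frequency `x_i` within each class of nodes of equal degree
`d_i`. A graph is reduced to its `degree_class_summary()`: class frequencies
`p_i`, and the row-stochastic mixing matrix `p_ij`, the probability that an
edge endpoint at a degree-`d_i` node leads to a degree-`d_j` node, computed
from the realized graph by counting ordered edge endpoints. The summary
always satisfies the edge balance `p_i d_i p_ij = p_j d_j p_ji`.

Per-class birth and death rates at class state `x` are

    T_i^+ = (1+s)/W * sum_j p_j p_ji x_j (1 - x_i)
    T_i^- =    1/W  * sum_j p_j p_ji (1 - x_j) x_i

with `W` the mean fitness (`transition_rates()`). Substituting these into
the backward Kolmogorov equation and linearizing the coefficients by
singular perturbation yields a fixation probability of Gaussian form

    P(x) = (1 - exp{-N sum_i p_i A_i x_i}) / (1 - exp{-N sum_i p_i A_i})

where the per-class exponents `A_i` solve a quadratic system, one equation
per degree class; the Bd and dB systems differ only by transposing
`p_i p_ij` with `p_j p_ji`, and the package implements them as one solver
parameterized by orientation (`solve_amplification()`). `A = 0` always
solves the system but is spurious; a damped Newton iteration therefore
starts at the exact single-class solution `A_i = 2s/(2+s)` and converges to
the nontrivial root (residual required below 1e-10; in practice 1e-12).
With a single degree class the solution collapses to the well-mixed
diffusion form — that identity is tested, not assumed.

### Closed-form amplification factors

For weak selection (`s ~ 1/N`) the exponent condenses into a single factor
`alpha` multiplying `s` in the well-mixed formula:

* `alpha_dB = <d>^2 / <d^2>` — death-Birth. A function of the degree
  distribution alone, bounded by 1 (Jensen), so at this order no
  degree-heterogeneous graph amplifies under dB, and the factor is invariant
  under degree-preserving rewiring.
* `alpha_Bd = <d^-1> mu_1 / mu_2`, with `mu_1 = sum p_j p_ji / d_i` and
  `mu_2 = sum p_j p_ji / d_i^2` — Birth-death. Depends on the mixing matrix
  as well: at fixed degrees, disassortative wiring raises it, assortative
  wiring lowers it. The 100-node star gives 1.9604 (amplifier); the same
  star gives `alpha_dB = 0.0396` (strong dB suppressor).

`classify_alpha()` thresholds at 1 (tolerance 1e-9): suppressor /
isothermal / amplifier.

The effect of one degree-preserving double edge swap that removes a
`(d_i, d_i)` and a `(d_j, d_j)` edge and creates two `(d_i, d_j)` edges is
predicted (in sign and relative magnitude) by

    delta_alpha_Bd ~ (1/d_i - 1/d_j)^2 (1/d_i + 1/d_j - mu_2/mu_1)

(`swap_effect_alpha_Bd()`). Because `mu_2/mu_1 <= 1/d_min`, swaps that
touch the lowest degree always increase `alpha_Bd`. The predictor is
asymptotic (large N); the exact change is always available by recomputing
`alpha_Bd()` on the swapped graph, and the test suite checks the two agree
in sign on at least 95 of 100 sampled moves.

### Regular perturbation for weakly coupled structures

Singular perturbation misplaces the suppression optimum when the exchange
of individuals between sub-populations is weak — the detour graph (a
complete cluster with one edge replaced by a long path) is the canonical
case. `solve_regular_perturbation()` instead expands to first order in `s`
with symmetric pair coefficients `A_ij` solving a linear system of
`|D|(|D|+1)/2` equations (3 unknowns for the two-degree detour graph).

One design choice deserves record. As printed, the expansion
`P = 1/N + s * sum p_i p_j A_ij` is inconsistent with the coefficient
system: for a single degree class the system gives `A = N/2`, which would
put `P` far above probability scale. The package pins the normalization
against the complete graph, evaluating `P = 1/N + (s/N) sum p_i p_j A_ij`;
a single class then yields `1/N + s/2`, the first-order well-mixed value
(the residual `s/(2N)` is second order under `s ~ 1/N`), and the reported
difference from well-mixed, `(s/N)(sum p_i p_j A_ij - N/2)`, is exactly
zero on the complete graph. With this anchor the detour-length sweep
reproduces the expected behaviour: zero difference at detour length 0,
a negative interior minimum, a rise back toward well-mixed as the graph
approaches a ring, and a minimum that deepens with `N`.

## Monte Carlo simulation and its oracle

`simulate_fixation()` runs replicate chains to absorption in compiled code.
Fitness-proportional choices reduce to two-type sampling with maintained
mutant/wild-type membership lists, so each update is O(degree). Times are
recorded in raw update steps and in steps/N (labelled "generations"),
averaged over fixing replicates only. Each replicate draws from an
independent RNG stream derived by hashing (master seed, replicate index),
so any single replicate is reproducible in isolation and results do not
depend on R's global RNG state. A step cap exists purely as a safety bound;
capped replicates are excluded with a warning because absorption is certain
on a connected graph.

The exact solver builds the full transition matrix over mutant sets as a
sparse system and solves it directly. The suite cross-validates simulation
against this oracle on ten small graphs under both rules and
`s in {0, 0.05, 0.2}` at three binomial standard errors, and checks the
neutral reproductive-value identities exactly: per-node fixation
probability proportional to `1/d_i` under Bd and to `d_i` under dB.

## Generators and the annealing rewirer

`generate_graph()` covers the families used in this literature: complete,
ring lattice, Erdős–Rényi, preferential attachment with tunable attachment
power `beta` (clique-of-`m` bootstrap; weights `degree^beta`, sampled
without replacement per new node — `beta` = 0 exponential tail, 1 power
law), random geometric and Waxman graphs on uniform or centred-Gaussian
point clouds, Watts–Strogatz small worlds, Holme–Kim power-law cluster
graphs, detour graphs and stars. Stochastic families are regenerated with
an incremented sub-seed (bounded attempts) until connected, because the
evolutionary process is undefined otherwise; the retry budget exhausting is
an error, not a silent fallback. Waxman decay constants and geometric radii
have no published defaults, so they are required parameters.

`anneal_assortativity()` explores graphs of fixed degree sequence by double
edge swaps with a Metropolis criterion on the degree Pearson correlation
`r`: improving swaps always accepted, worsening swaps with probability
`exp(-gamma |delta r|)`. (The printed form of this criterion in the source
literature has the sign such that maximization would accept decreases; the
package implements the stated goal, standard Metropolis on the configured
objective.) `1/gamma` is the annealing temperature; the schedule is a staged
geometric increase of `gamma`, fully user-configured since no rates are
published. Because degrees never change, the degree sums in `r` are
constant and the swap updates `r` in O(1) exact integer arithmetic — there
is no floating drift to correct. Connectivity is re-verified by BFS at a
configurable interval with rollback to the last verified state. Along any
trajectory the degree-class summary — hence `alpha_dB` — is exactly
invariant; only `p_ij` and `r` move, which is what makes the sampler the
right instrument for isolating mixing-pattern effects: across an annealing
ensemble, `r` and `alpha_Bd` are strongly negatively correlated.

## The spatial niche pipeline

Coordinate tables (`id, x, y[, z]` in micrometres) become graphs via
`build_spatial_graph()`: nodes are cells, and an edge joins cells closer
than `cutoff * unit`, where the unit is the sample's mean
nearest-neighbour distance (`mean_nn_distance()`; for the published HSC
data this unit is 62.72 um). "Shortest pairs" is read as each cell's
nearest-neighbour distance averaged over cells — the only reading
consistent with a single per-dataset unit. Expressing cutoffs in this unit
makes the graph invariant to coordinate rescaling. A probabilistic
exponential connection mode is also provided. Disconnected results reduce
to the giant component with the discarded count recorded; the published
analyses do not state their policy, so this is a documented package choice,
and downstream `N` is the component size. `cutoff_from_range()` converts a
biological interaction range into a cutoff multiple (1028 um over 62.72 um
gives 16.4); the range itself is an input, because combining a displacement
rate with a replicative lifetime is a modelling judgement that does not
reduce to linear scaling of the printed inputs.

The real bone-marrow datasets are external; `synth_points()` provides a
synthetic stand-in: a mixture of isotropic Gaussians truncated to a bounded
box. Defaults (400 cells, 2000 x 2000 um field, three hotspots of spread
300 um) give mean nearest-neighbour distances of roughly 40-60 um,
comparable to the published unit. `synth_samples()` builds a series of such
clouds at fixed cell density with extent growing as `sqrt(n)` — the way
tissue samples of different sizes actually relate — so that a cutoff
expressed in nearest-neighbour units stays local as `N` grows. What the
stand-in does **not** emulate: anatomical anisotropy (diaphysis versus
metaphysis geometry), exclusion-volume effects between cells, segmentation
noise, and the thin-slab 3D structure of the imaging volumes. Passing tests
on synthetic clouds therefore validate the pipeline and the qualitative
mechanism (smooth density gradients wire neighbours of similar degree,
producing assortative, suppressing graphs), not any quantitative claim
about real marrow.

`suppression_scan()` ties the pipeline together: per sample and cutoff it
builds the graph, estimates fixation by simulation, and subtracts the exact
well-mixed value at the component's size. `trend_stats()` fits ordinary
least squares of that difference on `N` and reports the Pearson
correlation and a Wald test of zero slope (statistic slope/SE, two-sided
normal p). On the synthetic series at the biologically calibrated cutoff
15, the majority of samples suppress under both rules (the test suite
asserts this), and the trend module recovers planted negative
size-vs-difference trends. Near the low-cutoff boundary (cutoff around
2-3) the Bd difference can sit at or slightly above the well-mixed value,
the analogue of the published exception at cutoff 2.

## Numerical choices and problem sizes

* Quadratic system: damped Newton from `A_i = 2s/(2+s)`, residual norm
  below 1e-12 required (hard failure above 1e-10, with a pointer to the
  regular-perturbation path).
* Regular perturbation: dense symmetric solve; reciprocal condition number
  reported, failure if numerically singular.
* Exact chain: sparse direct solve; enforced `N <= 14`.
* `r` for regular graphs is undefined and reported `NA`, never 0.
* Modularity (greedy heuristic) and clustering are descriptive statistics
  only; the theory never consumes them.
* Degree classes use exact degrees by default; an optional `bin_width`
  exists for graphs with very many distinct degrees and is off by default
  because the theory indexes by exact degree.
* The test suite validates simulations at 2e4-2e5 replicates on graphs of
  100-1200 nodes and oracle comparisons at 1e5 replicates on graphs of at
  most 10 nodes; these sizes make the full suite run in a few minutes while
  keeping binomial standard errors well below the effects being tested.

## Known limitations

The degree-class reduction assumes nodes of equal degree are topologically
exchangeable: community structure, motifs, and mixed
assortative/disassortative regions are invisible to it, and graphs built to
violate exchangeability will defeat the approximation. The closed-form
factors are first-order in `s`; strong selection can move a structure
across the amplifier/suppressor boundary. Analytic fixation *times* are out
of scope — times are estimated by simulation only.
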