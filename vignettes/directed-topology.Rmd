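---
title: "Directed topology of neural microcircuits: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed topology of neural microcircuits: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents what `dirtopo` computes, the model behind each
component, every default parameter and its unit, and the design decisions
taken where more than one convention is defensible.

## 1. The graph model

A `directed_graph` is a finite set of vertices `0..n-1` with directed edges
and no self-loops; a *reciprocal pair* (both `i -> j` and `j -> i`) is legal
and is treated as two distinct edges. Optional metadata: `positions`, an
`n x 3` matrix of soma coordinates in micrometres, and `labels`, a tibble of
per-vertex attributes (layer, morphological type, synapse class). Files are
read and written as edge-list CSV (`pre,post`, 0-based) or Matrix Market
coordinate files (1-based per the standard, rows = presynaptic).

Two scalar graph summaries:

- `signed_degree(g, v)` = indegree(v) − outdegree(v);
- `directionality(g)` = Σᵥ sd(v)², a measure of how hierarchically the edges
  are oriented. Over all tournaments on k vertices it is maximised exactly by
  the acyclic ones, with maximum (k−1)k(k+1)/3; this bound is verified
  exhaustively in the test suite for k ≤ 5.

## 2. Directed flag complexes

An (abstract) directed n-simplex is an ordered tuple (v₀, …, vₙ) of distinct
vertices with an edge vᵢ → vⱼ for every i < j; v₀ is its source and vₙ its
sink. The directed flag complex of a graph has these tuples as its
n-simplices. Note the ordering matters: with reciprocal edges, two tuples on
the same vertex set can both be simplices.

**Enumeration.** `flag_complex()` extends each simplex only at the sink, by
vertices in the intersection of the out-neighbourhoods of all current
members. Every directed simplex has a unique sink-extension history, so each
is generated exactly once; candidate lists are kept sorted, so the stored
tables are in lexicographic order and runs are byte-reproducible. The
enumerator is compiled (Rcpp) with a configurable `budget` (default 10⁷
simplices) that aborts with the offending dimension rather than exhausting
memory. `max_dim` truncates the census; truncated tables are flagged and
refuse operations whose answer would depend on the missing part
(maximality, Euler characteristic, the top Betti number).

**Maximality.** A simplex is maximal when it is not a face of any other
simplex. Because the stored tables are closed under faces, it suffices to
check whether a d-simplex occurs as a codimension-1 face of some
(d+1)-simplex; this insertion-based test (deleting any position, not only
the sink) is required because a simplex can be a face of a larger one via
insertion of a vertex in the middle of the order.

**Participation.** `participation()` counts, per vertex, the simplices
containing it in each dimension and the highest such dimension, and per
edge the number of *maximal* simplices of each dimension containing it —
the quantity against which pairwise spike correlations are compared.

**Sub-population censuses.** `subcomplex_census(g, filter)` takes the flag
complex of the induced subgraph on the selected vertices. This is a genuine
choice: one could instead restrict the full complex to simplices all of
whose vertices match the filter, which yields the same set of simplices
(a directed clique among selected vertices is unaffected by removing other
vertices), so the two conventions coincide here; the induced-subgraph
implementation is used because it is also cheaper.

## 3. Mod-2 homology

Chain groups Cₙ are GF(2)-vector spaces on the n-simplices; the boundary map
sends a simplex to the sum of its n+1 codimension-1 faces (no signs over
GF(2)). `boundary_matrices()` assembles sparse Dₙ of shape
|Sₙ₋₁| × |Sₙ| with lexicographically sorted bases, so matrices are
reproducible. Ranks are computed by column-reduction Gaussian elimination on
64-bit-packed columns in C++. Betti numbers:

- β₀ = |S₀| − rank(D₁) (equals the number of weakly connected components),
- βₙ = null(Dₙ) − rank(Dₙ₊₁) for intermediate n,
- β_top = null(D_top),

and χ = Σ(−1)ⁿ|Sₙ| = Σ(−1)ⁿβₙ, asserted as a property in the tests.

**Coskeleton shortcut.** For k ≥ 1, `top_betti_via_coskeleton(st, k)`
computes βₖ on the k-coskeleton (all simplices of dimension ≥ k, closed
downward by codimension-1 faces). The kernel of ∂ₖ and the image of ∂ₖ₊₁
only involve k- and (k+1)-simplices and their immediate faces, all of which
the coskeleton contains, so the value is exact while the (typically enormous)
low-dimensional part of the complex is never materialised.

**Truncation policy.** On a `max_dim`-truncated table, `betti_numbers()`
computes every dimension whose neighbourhood is complete and returns `NA`
for the top dimension and for χ; `euler_characteristic()` refuses truncated
tables outright.

## 4. Null connectivity models

All controls preserve vertex count and total edge count exactly and are
deterministic under their `seed`.

- `er_control(reference, seed)`: redraw the m edges uniformly without
  replacement from the n(n−1) ordered off-diagonal pairs. On such graphs the
  expected number of directed k-simplices is P(n, k+1) · p^(k(k+1)/2) with
  p = m / (n(n−1)); the test suite checks the k = 2 case against 200
  simulated controls. (Fixing the edge count exactly, rather than
  independently sampling each edge, biases simplex counts slightly downward;
  at the sizes tested the bias is an order of magnitude below the sampling
  error.)
- `pr_control(candidate, target, seed)`: uniform prune of a permissive
  candidate graph down to the target edge count. The candidate stands in
  for any structural prior (e.g. axon–dendrite apposition within a distance
  threshold); the operation only assumes it contains the target density.
- `gb_control(reference, type_col, seed, distance_bin = 75, max_retries =
  100)`: for each (presynaptic type, postsynaptic type) block, each
  connection's target is resampled uniformly among vertices of the same
  postsynaptic type whose distance from the source falls in the same
  `distance_bin`-micrometre bin (default 75 µm), preserving per-block edge
  counts and per-block binned soma-distance histograms exactly. Collisions
  with already-placed edges are resolved by bounded retry (default 100
  draws), after which the original target is retained and logged; retaining
  the original is also the fallback when a bin offers no alternative target.
  Per-connection resampling (rather than a within-block permutation) was
  chosen because it matches the generative description of the model;
  the keep-original collision policy is this package's own choice and is
  surfaced via the `"kept_original"` attribute so its frequency can be
  audited.

## 5. Activity layer

**Spike trains.** `spike_train_set` stores one row per spike (0-based
neuron, 1-based trial, time in ms within [0, T)); times must be strictly
increasing within a train.

**PSTH.** `psth(spikes, bin_size = 25)` bins each neuron's spikes into
25 ms windows (default) and averages counts over trials; spikes past the
last complete bin are dropped.

**Correlation.** `correlation_matrix()` computes the normalised covariance
Rᵢⱼ = Cᵢⱼ / √(Cᵢᵢ Cⱼⱼ) of PSTH rows; PSTHs recorded under different stimuli
may be concatenated column-wise first. Rows with zero variance
(non-responding neurons) cannot be normalised; they are masked `NA` and
excluded from every downstream mean. Exclusion is the conservative choice —
imputing zero correlation would dilute group means with fabricated values.

**Transmission-response graphs.** `tr_series(spikes, structure, dt1 = 5,
dt2 = 10)` splits a single-trial recording into bins of Δt₁ = 5 ms. Edge
j → k is active in bin n when j spikes at some s in [nΔt₁, (n+1)Δt₁) *and*
k spikes strictly within (s, s + Δt₂), Δt₂ = 10 ms. Two deliberate
readings of this definition:

- the postsynaptic spike must follow *the same* presynaptic spike that
  landed in the bin (the window is anchored at s, not at the bin), so a
  response window may extend past the bin boundary; and
- the inequalities are strict: a simultaneous pair or a gap of exactly Δt₂
  does not count.

Every TR matrix is by construction a subgraph of the structural adjacency
(asserted in the tests against a brute-force triple-loop oracle).

**Analyses.**

- `active_simplex_enrichment()` reports per bin the fraction of structural
  edges active and the fraction of structural k-simplices fully active, next
  to the same fraction in controls with equally many edges drawn uniformly
  from the structural edge set. Both raw counts and fractions are emitted,
  since the natural normalisation (structural totals) is itself a choice
  one may want to revisit; the controls make the comparison
  normalisation-free.
- `edge_participation_correlation(r, prof, min_samples = 1000)` groups
  edges by the number of maximal simplices per dimension they belong to and
  reports mean R per group, omitting groups below `min_samples` (default
  1000; configurable because synthetic fixtures are far smaller than a
  cortical reconstruction).
- `position_pair_correlation(r, maximal)` reports mean R for three
  designated pairs per maximal simplex — (first, second), (source, sink),
  (last two) — per dimension. In dimension 1 all three coincide with the
  edge itself, which serves as a built-in consistency check.
- `psth_sweep()` recomputes mean pairwise correlation across bin sizes
  (10, 25, 50, 100, 250, 500 ms) to expose sensitivity to the binning.

## 6. Synthetic fixtures: scope and limits

The generators provide controllable inputs, not biophysics; no membrane
potentials or synaptic dynamics are simulated.

- `make_circuit(circuit_spec(...))` places somata uniformly in per-layer
  depth slabs (defaults: four layers of 60/120/120/100 neurons between
  depths 0–1600 µm over a 400 µm square footprint), labels each neuron
  excitatory with probability 0.86, and connects each ordered pair
  independently with probability given by a kernel of soma distance and
  synapse classes. The default `exponential_kernel(p0 = 0.25, scale = 180,
  inh_factor = 1.2)` (zero-distance probability 0.25, e-fold decay length
  180 µm, inhibitory presynaptic boost 1.2) gives local clustering strong
  enough to separate the geometric circuit from its uniform control in
  desk-scale runs.
- `known_complex(name)` builds reference complexes with analytically known
  topology: `simplex-n` (acyclic tournament, β = (1, 0, …)), `cycle-3`
  (β = (1, 1)), `octahedron-sphere` (eight directed triangles tiling a
  2-sphere, β = (1, 0, 1)), and disjoint unions thereof.
- `make_spikes(spike_gen_spec(...))` layers ensemble coactivation on
  background Poisson spiking. Defaults: duration 2000 ms, one trial,
  baseline 2 Hz, one event stream of 1 Hz per ensemble, jitter 2 ms. Each
  event injects one spike per participating member with cumulative
  exponential inter-member delays (source earliest, sink latest, mean gap =
  `jitter`), so transmission runs along the simplex orientation — exactly
  the statistical structure the TR analysis is designed to detect. The
  optional `participation` ramp (probability of joining an event, linear
  from source to sink) reproduces the situation where sink-adjacent members
  receive the most shared drive, which is what makes last-pair correlations
  exceed first-pair correlations in dimensions ≥ 2. Limits: spike count
  distributions are Poisson mixtures, not renewal processes; refractory
  periods are ignored (coincident duplicates are dropped); correlations are
  induced only through shared events.
- `sample_patch()` emulates a multi-patch experiment: a 200 × 200 × 20 µm
  box placed uniformly inside the circuit's bounding box, candidate cells
  optionally filtered by label, a random fraction kept (default 0.5,
  modelling patching failure), capped at 12 cells, and the directed simplex
  census of the induced subgraph recorded per experiment.

Problem sizes throughout the package's tests (circuits of 50–240 neurons,
recordings of seconds to a minute) are the package's own choices, selected
so each property is decidable quickly while leaving the algorithms'
asymptotic behaviour untouched.

## 7. Reproducibility

Every stochastic function takes an explicit integer seed and uses it in an
isolated RNG scope, so calls neither disturb nor depend on the session RNG
state. The CLI writes a JSON manifest (command, parameters, package version,
input checksums) next to every output, making each run reproducible from
the manifest alone.
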