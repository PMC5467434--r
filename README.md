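# dirtopo

Directed-graph topology for neural microcircuits: directed flag complexes,
simplex censuses, mod-2 homology, connectome null models, and the
structure–function layer that links spike-train correlations to simplex
membership.

## The scientific problem

Synaptic connectivity is directed: information flows from a presynaptic to a
postsynaptic neuron. Classical network statistics (degree distributions,
clustering) ignore that arrow, and undirected topology misses the feed-forward
motifs that cortical microcircuits are built from. The objects of interest
here are **directed simplices**: sets of n+1 neurons that are all-to-all
connected *with a consistent direction*, i.e. the neurons can be ordered so
every connection points from earlier to later. A directed n-simplex has a
unique **source** (sends to all others) and a unique **sink** (receives from
all others) and is the natural unit of feed-forward processing inside a
recurrent graph.

The **directed flag complex** of a connectivity graph is the simplicial
complex whose n-simplices are exactly these directed (n+1)-cliques. Two
families of quantities summarise it:

- the **simplex census** — how many directed simplices exist per dimension,
  how many are *maximal* (not contained in a larger one), and how vertices
  and edges participate in them; and
- **mod-2 homology** — Betti numbers βₙ counting the n-dimensional cavities
  enclosed by simplices, with the Euler characteristic
  χ = Σ(−1)ⁿ|Sₙ| = Σ(−1)ⁿβₙ as a consistency check.

Because any single graph statistic is meaningless without a reference, the
package ships the three standard control models matched to a reference
connectome: a uniform directed Erdős–Rényi control at identical density
(`er_control`), a pruned permissive-candidate control (`pr_control`), and a
shuffle that preserves per-cell-type connection counts and the distribution
of soma distances of connected pairs in 75 µm bins (`gb_control`).

Finally, the activity layer asks whether this structure matters for function:
spike trains are reduced to peristimulus time histograms (PSTHs), pairwise
normalised covariances, and **transmission-response (TR) graphs** — per time
bin, the subgraph of structural edges whose presynaptic neuron spiked in the
bin and whose postsynaptic neuron spiked within a short window after it.
Analyses relate pairwise correlation to the number and dimension of maximal
simplices an edge belongs to, to the pair's position inside a simplex
(source–sink, first two, last two), and test whether TR graphs contain more
coherent simplices than their edge count alone predicts.

## Worked example

Generate a small layered circuit with distance-dependent connectivity, count
its directed simplices, compute its homology, and compare against a
density-matched uniform control:

```r
library(dirtopo)

g <- make_circuit(circuit_spec(
  n_per_layer = c(40, 60, 50), layer_depths = c(0, 200, 500, 800),
  lateral = 300, seed = 7))
g
#> <directed_graph: 150 vertices, 1305 edges, positions, labels>

st <- flag_complex(g)
simplex_counts(st)
#> # A tibble: 5 × 2
#>   dimension count
#>       <int> <int>
#> 1         0   150
#> 2         1  1305
#> 3         2   917
#> 4         3    81
#> 5         4     3

betti_numbers(st)
#> <betti_profile: beta = (1, 358, 41, 0, 0), chi = -316>

directionality(g)
#> [1] 2272

er <- er_control(g, seed = 1)
c(reconstruction = st$counts[3], uniform_control = flag_complex(er)$counts[3])
#> reconstruction uniform_control
#>            917             667
```

The geometric circuit carries ~40% more directed 2-simplices than a uniform
directed graph of identical size and density — distance-dependent
connectivity clusters edges into feed-forward motifs.

Exact combinatorics of small motifs and reference complexes:

```r
motif_census(4)
#> # A tibble: 1 × 4
#>   n_total_configurations n_unidirectional n_acyclic n_cyclic
#>                    <int>            <int>     <int>    <int>
#> 1                    729               64        24       40

betti_numbers(flag_complex(known_complex("octahedron-sphere")))
#> <betti_profile: beta = (1, 0, 1), chi = 2>
```

And the structure–function direction: spike trains whose coactivation is
concentrated on directed simplices produce transmission-response graphs with
far more complete simplices than matched random edge sets:

```r
fix <- known_complex("disjoint-union(simplex-3, simplex-3)")
mx  <- maximal_simplices(flag_complex(fix))
ens <- lapply(seq_len(nrow(mx$simplices[[4]])), function(r) mx$simplices[[4]][r, ])
sp  <- make_spikes(spike_gen_spec(n_neurons = 8, duration = 10000,
                                  baseline_rate = 1, ensembles = ens,
                                  coactivation_rate = 2, jitter = 1, seed = 3))
tr  <- tr_series(sp, fix)                       # dt1 = 5 ms, dt2 = 10 ms
enr <- active_simplex_enrichment(tr, fix, dims = 2, n_random = 10, seed = 4)
dplyr::summarise(dplyr::filter(enr, n_active_edges > 0),
                 bins = dplyr::n(),
                 tr_simplex_fraction = mean(simplex_fraction),
                 control_fraction = mean(control_simplex_fraction))
#> # A tibble: 1 × 3
#>    bins tr_simplex_fraction control_fraction
#>   <int>               <dbl>            <dbl>
#> 1    53               0.325           0.0696
```

All censuses and analysis results are tibbles (`tidy()`/`glance()` methods
are provided for the S3 containers), so they drop straight into dplyr/ggplot2
pipelines; `autoplot()` methods and `plot_enrichment()` /
`plot_edge_participation()` give quick visual summaries.

A command-line interface covering the same operations ships at
`system.file("cli", "dirtopo.R", package = "dirtopo")`; every run writes a
JSON manifest with parameters, seeds, package version and input checksums.

## Methods

The methods vignette (`vignettes/directed-topology.Rmd`) documents the model
and its assumptions, all default parameters and their units, the numerical
choices (enumeration order, GF(2) rank algorithm, coskeleton shortcut for top
Betti numbers), and the design decisions taken where conventions diverge.
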