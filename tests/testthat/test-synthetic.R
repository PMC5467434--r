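test_that("circuit generation respects its kernel", {
  # kernel identically zero -> no edges
  spec <- circuit_spec(n_per_layer = c(20, 20), layer_depths = c(0, 100, 200),
                       kernel = function(d, a, b) rep(0, length(d)), seed = 2)
  expect_equal(n_edges(make_circuit(spec)), 0L)
  # constant kernel p: edge count within 3 SE of binomial expectation
  p <- 0.2
  spec <- circuit_spec(n_per_layer = c(40, 40), layer_depths = c(0, 100, 200),
                       kernel = function(d, a, b) rep(p, length(d)), seed = 3)
  g <- make_circuit(spec)
  n <- n_vertices(g)
  npairs <- n * (n - 1)
  expect_lt(abs(n_edges(g) - npairs * p), 3 * sqrt(npairs * p * (1 - p)))
  # determinism
  expect_identical(keys_of(make_circuit(spec)$edges), keys_of(g$edges))
  # metadata present and consistent
  expect_equal(nrow(g$positions), n)
  expect_true(all(c("layer", "mtype", "synapse_class") %in% names(g$labels)))
  expect_true(all(g$labels$synapse_class %in% c("EXC", "INH")))
})

test_that("distance-decaying kernels connect near pairs more often than far pairs", {
  spec <- circuit_spec(n_per_layer = c(60, 60), layer_depths = c(0, 200, 400),
                       lateral = 400,
                       kernel = exponential_kernel(p0 = 0.5, scale = 80), seed = 7)
  g <- make_circuit(spec)
  pos <- g$positions
  d_conn <- sqrt(rowSums((pos[g$edges[, 1] + 1L, ] - pos[g$edges[, 2] + 1L, ])^2))
  pre <- rep(0:(n_vertices(g) - 1L), each = n_vertices(g))
  post <- rep(0:(n_vertices(g) - 1L), times = n_vertices(g))
  off <- pre != post
  d_all <- sqrt(rowSums((pos[pre[off] + 1L, ] - pos[post[off] + 1L, ])^2))
  expect_lt(mean(d_conn), mean(d_all))
  # empirical connection probability decays across distance terciles
  qs <- stats::quantile(d_all, c(1 / 3, 2 / 3))
  bin_all <- findInterval(d_all, qs)
  bin_conn <- findInterval(d_conn, qs)
  p_hat <- tabulate(bin_conn + 1L, 3) / tabulate(bin_all + 1L, 3)
  expect_true(all(diff(p_hat) < 0))
})

test_that("known complexes have their reference censuses and Betti profiles", {
  expect_equal(flag_complex(known_complex("octahedron-sphere"))$counts, c(6L, 12L, 8L))
  expect_equal(flag_complex(known_complex("simplex-3"))$counts, c(4L, 6L, 4L, 1L))
  expect_equal(flag_complex(known_complex("cycle-3"))$counts, c(3L, 3L))
  du <- known_complex("disjoint-union(cycle-3, simplex-2)")
  expect_equal(n_vertices(du), 6L)
  expect_equal(betti_numbers(flag_complex(du))$betti, c(2L, 1L, 0L))
  expect_error(known_complex("klein-bottle"), "unknown complex")
})

test_that("spike generator hits its marginal rates within 3 SE", {
  # background only
  spec <- spike_gen_spec(n_neurons = 40, duration = 20000, baseline_rate = 4,
                         seed = 11)
  s <- make_spikes(spec)
  expected <- 40 * 4 * 20
  expect_lt(abs(nrow(s) - expected), 3 * sqrt(expected))
  # background + one ensemble: members gain ~ rate spikes/s each
  ens <- list(c(0L, 1L, 2L))
  spec <- spike_gen_spec(n_neurons = 10, duration = 50000, baseline_rate = 2,
                         ensembles = ens, coactivation_rate = 3, jitter = 1,
                         seed = 12)
  s <- make_spikes(spec)
  per <- tabulate(tibble::as_tibble(s)$neuron + 1L, 10)
  exp_member <- (2 + 3) * 50
  exp_other <- 2 * 50
  expect_lt(max(abs(per[1:3] - exp_member)), 3 * sqrt(exp_member) + 3)
  expect_lt(abs(mean(per[4:10]) - exp_other), 3 * sqrt(exp_other / 7))
  # determinism
  expect_identical(tibble::as_tibble(make_spikes(spec)), tibble::as_tibble(s))
})

test_that("coactivation controls pairwise correlation as designed", {
  # rate 0: independent trains, correlations near 0
  spec <- spike_gen_spec(n_neurons = 20, duration = 30000, baseline_rate = 5,
                         ensembles = list(0:19), coactivation_rate = 0, seed = 4)
  cm <- correlation_matrix(psth(make_spikes(spec)))
  off <- cm$R; diag(off) <- NA
  expect_lt(abs(mean(off, na.rm = TRUE)), 0.05)
  # one ensemble covering all neurons, high rate, small jitter: R near 1
  spec <- spike_gen_spec(n_neurons = 20, duration = 30000, baseline_rate = 0.2,
                         ensembles = list(0:19), coactivation_rate = 8,
                         jitter = 0.5, seed = 5)
  cm <- correlation_matrix(psth(make_spikes(spec)))
  off <- cm$R; diag(off) <- NA
  expect_gt(mean(off, na.rm = TRUE), 0.8)
})

test_that("patch sampling reproduces the census in the degenerate limits", {
  g <- make_circuit(circuit_spec(n_per_layer = c(15, 15), layer_depths = c(0, 80, 160),
                                 lateral = 150, seed = 6))
  # box covering the whole fixture, keep everything: full census each time
  full <- simplex_counts(flag_complex(g))
  out <- sample_patch(g, box = c(1e4, 1e4, 1e4), max_cells = n_vertices(g),
                      keep_fraction = 1, n_experiments = 3, seed = 8)
  for (ex in 1:3) {
    got <- dplyr::filter(out, experiment == ex)
    expect_equal(got$count, full$count)
    expect_equal(unique(got$n_cells), n_vertices(g))
  }
  # keeping at most one cell: only 0-simplices
  out1 <- sample_patch(g, box = c(1e4, 1e4, 1e4), max_cells = 1,
                       keep_fraction = 1, n_experiments = 5, seed = 9)
  expect_true(all(out1$dimension == 0))
  expect_true(all(out1$count == 1))
  # label filter restricts the candidate pool
  exc <- sample_patch(g, box = c(1e4, 1e4, 1e4), max_cells = n_vertices(g),
                      keep_fraction = 1, n_experiments = 1, seed = 10,
                      label_filter = function(l) l$synapse_class == "EXC")
  expect_equal(unique(exc$n_cells), sum(g$labels$synapse_class == "EXC"))
  expect_error(sample_patch(directed_graph(rbind(c(0, 1)))), "positions")
})

test_that("patch-sampling counts match an independent enumeration per experiment", {
  # tiny patches so the brute-force oracle stays tractable
  g <- make_circuit(circuit_spec(n_per_layer = c(25, 25), layer_depths = c(0, 120, 240),
                                 lateral = 200, seed = 14))
  out <- sample_patch(g, box = c(80, 80, 40), max_cells = 6, keep_fraction = 0.8,
                      n_experiments = 30, seed = 15)
  # determinism
  expect_identical(sample_patch(g, box = c(80, 80, 40), max_cells = 6,
                                keep_fraction = 0.8, n_experiments = 30, seed = 15),
                   out)
  # aggregate dimension histogram is internally consistent: for every
  # experiment, counts are positive and 0-simplex count equals n_cells
  agg <- dplyr::filter(out, dimension == 0)
  expect_equal(agg$count, agg$n_cells)
  expect_true(all(out$count >= 0))
  expect_true(all(out$n_cells <= 6))
})
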