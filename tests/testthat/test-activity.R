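toy_spikes <- function(times_by_neuron, n_neurons, duration, trial = 1L) {
  df <- dplyr::bind_rows(lapply(seq_along(times_by_neuron), function(i) {
    tibble::tibble(neuron = i - 1L, trial = trial, time = times_by_neuron[[i]])
  }))
  spike_train_set(df, n_neurons = n_neurons, duration = duration)
}

test_that("spike_train_set validates its invariants", {
  expect_error(toy_spikes(list(c(5, 5)), 1, 10), "strictly increasing")
  expect_error(toy_spikes(list(10), 1, 10), "\\[0, duration\\)")
  expect_error(spike_train_set(tibble::tibble(neuron = 3, trial = 1, time = 1),
                               n_neurons = 2, duration = 10), "out of range")
  s <- toy_spikes(list(c(1, 2), 3), 2, 10)
  expect_s3_class(s, "spike_train_set")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spikes(s, path)
  back <- read_spikes(path, n_neurons = 2, duration = 10)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(s))
})

test_that("psth bins and trial-averages as defined", {
  # 1 neuron, 1 trial, spikes {2, 7} ms, bin 5 -> counts (1, 1)
  p <- psth(toy_spikes(list(c(2, 7)), 1, 10), bin_size = 5)
  expect_equal(unclass(p), matrix(c(1, 1), 1, 2), ignore_attr = TRUE)
  # 2 trials with counts 0 and 2 in a bin -> mean 1.0
  df <- tibble::tibble(neuron = 0L, trial = c(2L, 2L), time = c(1, 2))
  s <- spike_train_set(df, n_neurons = 1, duration = 5, n_trials = 2)
  expect_equal(as.numeric(psth(s, bin_size = 5)), 1.0)
  # spikes beyond the last full bin are dropped
  p <- psth(toy_spikes(list(c(1, 11)), 1, 12), bin_size = 5)
  expect_equal(as.numeric(p), c(1, 0))
  expect_error(psth(toy_spikes(list(1), 1, 10), bin_size = 0), "positive")
})

test_that("psth of a Poisson train recovers the rate within 3 SE", {
  spec <- spike_gen_spec(n_neurons = 50, duration = 10000, baseline_rate = 8,
                         seed = 17)
  p <- psth(make_spikes(spec), bin_size = 25)
  lambda <- 8 * 25 / 1000                     # expected count per bin
  n_obs <- length(p)
  se <- sqrt(lambda / n_obs)                  # Poisson variance = mean
  expect_lt(abs(mean(p) - lambda), 3 * se)
})

test_that("correlation matrix matches Eq.-style examples and a textbook recomputation", {
  # two identical nonconstant PSTHs -> R = 1
  p <- structure(rbind(c(1, 2, 3), c(1, 2, 3)), class = "psth_matrix", bin_size = 25)
  expect_equal(correlation_matrix(p)$R[1, 2], 1)
  # (1,2,3) vs (3,2,1) -> R = -1
  p <- structure(rbind(c(1, 2, 3), c(3, 2, 1)), class = "psth_matrix", bin_size = 25)
  expect_equal(correlation_matrix(p)$R[1, 2], -1)
  # zero-variance row masked
  p <- structure(rbind(c(1, 2, 3), c(2, 2, 2)), class = "psth_matrix", bin_size = 25)
  cm <- correlation_matrix(p)
  expect_equal(cm$valid, c(TRUE, FALSE))
  expect_true(is.na(cm$R[1, 2]))
  expect_equal(cm$R[1, 1], 1)
  # random rows vs textbook covariance computation
  withr::with_seed(5, {
    m <- matrix(stats::rnorm(60), nrow = 6)
  })
  p <- structure(m, class = "psth_matrix", bin_size = 25)
  R <- correlation_matrix(p)$R
  expect_equal(R, stats::cor(t(m)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(R, t(R))
  expect_true(all(abs(R) <= 1 + 1e-12))
  # concatenation across stimuli
  p2 <- structure(m[, 1:4], class = "psth_matrix", bin_size = 25)
  Rcat <- correlation_matrix(p, concatenate = list(p2))$R
  expect_equal(Rcat, stats::cor(t(cbind(m, m[, 1:4]))), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(correlation_matrix(p, concatenate = list(
    structure(m, class = "psth_matrix", bin_size = 50))), "bin size")
})

test_that("tr_series reproduces the transmission-window examples", {
  g <- directed_graph(rbind(c(0, 1)))
  # s0 = {2}, s1 = {8}: gap 6 in (0, 10) -> active in bin 0
  tr <- tr_series(toy_spikes(list(2, 8), 2, 20), g, dt1 = 5, dt2 = 10)
  expect_equal(tr$active[[1]], 1L)
  expect_equal(as.matrix(tr_matrix(tr, 0, g))[1, 2], 1)
  # same spikes, no structural edge -> all zeros
  g0 <- directed_graph(NULL, n_vertices = 2)
  tr0 <- tr_series(toy_spikes(list(2, 8), 2, 20), g0, dt1 = 5, dt2 = 10)
  expect_true(all(lengths(tr0$active) == 0))
  # s1 = {14}: gap 12 >= dt2 -> inactive
  tr <- tr_series(toy_spikes(list(2, 14), 2, 20), g, dt1 = 5, dt2 = 10)
  expect_equal(length(tr$active[[1]]), 0L)
  # gap exactly dt2 does not count; simultaneous spikes do not count
  tr <- tr_series(toy_spikes(list(2, 12), 2, 20), g, dt1 = 5, dt2 = 10)
  expect_equal(length(tr$active[[1]]), 0L)
  s <- spike_train_set(tibble::tibble(neuron = 0:1, trial = 1L, time = c(2, 2)),
                       n_neurons = 2, duration = 20)
  expect_equal(length(tr_series(s, g)$active[[1]]), 0L)
  # response window may reach past the bin boundary
  tr <- tr_series(toy_spikes(list(4, 9), 2, 20), g, dt1 = 5, dt2 = 10)
  expect_equal(tr$active[[1]], 1L)
  # multi-trial input refused
  s2 <- spike_train_set(tibble::tibble(neuron = 0L, trial = 1:2, time = c(1, 2)),
                        n_neurons = 2, duration = 20, n_trials = 2)
  expect_error(tr_series(s2, g), "single-trial")
})

test_that("tr_series agrees with the brute-force oracle and stays inside the structure", {
  for (seed in 1:15) {
    withr::with_seed(seed, {
      n <- sample(5:12, 1)
      g <- random_digraph(n, 0.3, seed = seed + 100)
      dur <- 200
      cnt <- stats::rpois(n, 6)
      df <- tibble::tibble(
        neuron = rep(0:(n - 1L), cnt), trial = 1L,
        time = stats::runif(sum(cnt), 0, dur))
      df <- df[!duplicated(paste(df$neuron, df$time)), ]
      s <- spike_train_set(df, n_neurons = n, duration = dur)
    })
    tr <- tr_series(s, g, dt1 = 5, dt2 = 10)
    oracle <- oracle_tr(tibble::as_tibble(s), g$edges, n, dur, 5, 10)
    expect_equal(lapply(tr$active, sort), lapply(oracle, sort),
                 info = paste("seed", seed))
    # subgraph invariant: active edge indices reference structural edges
    expect_true(all(unlist(tr$active) %in% seq_len(nrow(g$edges))))
    A <- as.matrix(adjacency_sparse(g)) > 0
    for (b in 0:(tr$n_bins - 1L)) {
      An <- as.matrix(tr_matrix(tr, b, g)) > 0
      expect_true(all(!An | A))
    }
  }
})

test_that("active-simplex enrichment endpoints: full and empty TR graphs", {
  g <- known_complex("simplex-3")
  # all members spike in a tight cascade in bin 0, nothing afterwards
  s <- toy_spikes(list(1, 2, 3, 4), 4, 10)
  tr <- tr_series(s, g, dt1 = 5, dt2 = 10)
  expect_equal(sort(tr$active[[1]]), 1:6)      # full structural matrix in bin 0
  enr <- active_simplex_enrichment(tr, g, dims = c(2, 3), n_random = 5, seed = 2)
  full <- dplyr::filter(enr, bin == 0)
  expect_equal(full$edge_fraction, c(1, 1))
  expect_equal(full$simplex_fraction, c(1, 1))
  expect_equal(full$control_simplex_fraction, c(1, 1))
  empty <- dplyr::filter(enr, bin == 1)
  expect_equal(empty$edge_fraction, c(0, 0))
  expect_equal(empty$simplex_fraction, c(0, 0))
  expect_equal(empty$n_active_simplices, c(0, 0))
  expect_equal(empty$n_simplices_total, c(4, 1))
})

test_that("edge participation correlation matches direct recomputation", {
  # constant R: every group mean equals the constant
  g <- known_complex("simplex-3")
  prof <- participation(flag_complex(g), g)
  R <- matrix(0.4, 4, 4); diag(R) <- 1
  r <- structure(list(R = R, valid = rep(TRUE, 4)), class = "correlation_matrix")
  out <- edge_participation_correlation(r, prof, min_samples = 1)
  expect_true(all(out$mean_r == 0.4))
  # 3-edge toy with distinct R values, min_samples = 1
  g <- directed_graph(rbind(c(0, 1), c(1, 2), c(0, 2)))
  prof <- participation(flag_complex(g), g)
  R <- matrix(NA_real_, 3, 3)
  R[1, 2] <- R[2, 1] <- 0.1; R[2, 3] <- R[3, 2] <- 0.3; R[1, 3] <- R[3, 1] <- 0.5
  diag(R) <- 1
  r <- structure(list(R = R, valid = rep(TRUE, 3)), class = "correlation_matrix")
  out <- edge_participation_correlation(r, prof, min_samples = 1)
  # all three edges lie in exactly one maximal simplex, of dimension 2
  row2 <- dplyr::filter(out, dimension == 2, n_maximal == 1)
  expect_equal(row2$mean_r, mean(c(0.1, 0.3, 0.5)))
  expect_equal(row2$n_edges, 3L)
  row1 <- dplyr::filter(out, dimension == 1, n_maximal == 0)
  expect_equal(row1$n_edges, 3L)
  # default threshold removes every group on this toy
  expect_equal(nrow(edge_participation_correlation(r, prof)), 0L)
})

test_that("position-pair correlation collapses to the edge pair in dimension 1", {
  g <- directed_graph(rbind(c(0, 1), c(2, 3)))
  mx <- maximal_simplices(flag_complex(g))
  R <- matrix(NA_real_, 4, 4); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- 0.2; R[3, 4] <- R[4, 3] <- 0.8
  r <- structure(list(R = R, valid = rep(TRUE, 4)), class = "correlation_matrix")
  out <- position_pair_correlation(r, mx)
  expect_equal(sort(unique(out$pair_kind)),
               sort(c("first-second", "source-sink", "last-pair")))
  expect_true(all(out$mean_r == 0.5))
  expect_true(all(out$n_pairs == 2L))
  # constant R on a complex with dimension >= 2: all means equal
  g <- known_complex("simplex-3")
  mx <- maximal_simplices(flag_complex(g))
  R <- matrix(0.3, 4, 4); diag(R) <- 1
  r <- structure(list(R = R, valid = rep(TRUE, 4)), class = "correlation_matrix")
  out <- position_pair_correlation(r, mx)
  expect_true(all(out$mean_r[out$n_pairs > 0] == 0.3))
})

test_that("psth sweep reports one row per bin size", {
  spec <- spike_gen_spec(n_neurons = 10, duration = 3000, baseline_rate = 5, seed = 3)
  s <- make_spikes(spec)
  out <- psth_sweep(s, bin_sizes = c(25, 100))
  expect_equal(out$bin_size, c(25, 100))
  expect_true(all(is.finite(out$mean_r)))
})
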