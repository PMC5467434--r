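#' Spike train container
#'
#' Spike times are stored in long form: one row per spike, with 0-based
#' neuron id, 1-based trial index, and time in milliseconds within `[0, T)`.
#' Times must be strictly increasing within each (neuron, trial) train.
#'
#' @param spikes a data frame with columns `neuron`, `trial`, `time`.
#' @param n_neurons total neuron count (ids `0..n_neurons-1`).
#' @param duration trial duration T in ms.
#' @param n_trials number of trials (defaults to `max(trial)`).
#' @param stimulus_id optional label.
#' @return a `spike_train_set` (a tibble subclass with metadata attributes).
#' @export
spike_train_set <- function(spikes, n_neurons, duration, n_trials = NULL,
                            stimulus_id = NULL) {
  spikes <- tibble::as_tibble(spikes)[, c("neuron", "trial", "time")]
  if (nrow(spikes) > 0) {
    if (min(spikes$time) < 0 || max(spikes$time) >= duration) {
      rlang::abort("spike times must lie in [0, duration).")
    }
    if (min(spikes$neuron) < 0 || max(spikes$neuron) >= n_neurons) {
      rlang::abort("neuron id out of range.")
    }
    spikes <- dplyr::arrange(spikes, .data$trial, .data$neuron, .data$time)
    same <- spikes$neuron == dplyr::lag(spikes$neuron) &
      spikes$trial == dplyr::lag(spikes$trial) &
      spikes$time <= dplyr::lag(spikes$time)
    if (any(same, na.rm = TRUE)) {
      rlang::abort("spike times must be strictly increasing within a train.")
    }
  }
  structure(spikes,
            class = c("spike_train_set", class(spikes)),
            n_neurons = as.integer(n_neurons),
            duration = as.numeric(duration),
            n_trials = as.integer(n_trials %||%
                                    ifelse(nrow(spikes) > 0, max(spikes$trial), 1L)),
            stimulus_id = stimulus_id)
}

#' Read / write spike trains as CSV
#'
#' Columns `neuron` (0-based id), `trial` (1-based), `time` (ms).
#' @param path file path.
#' @param n_neurons,duration,n_trials,stimulus_id see [spike_train_set()].
#' @return a `spike_train_set` ([read_spikes()]) or `path` ([write_spikes()]).
#' @export
read_spikes <- function(path, n_neurons, duration, n_trials = NULL,
                        stimulus_id = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  spike_train_set(df, n_neurons = n_neurons, duration = duration,
                  n_trials = n_trials, stimulus_id = stimulus_id)
}

#' @rdname read_spikes
#' @param spikes a `spike_train_set`.
#' @export
write_spikes <- function(spikes, path) {
  readr::write_csv(tibble::as_tibble(spikes), path)
  invisible(path)
}

#' Peri-stimulus time histogram matrix
#'
#' Bins each neuron's spikes into windows of `bin_size` ms and averages the
#' counts over trials: entry (j, b) is the mean number of spikes of neuron j
#' in `[b*bin, (b+1)*bin)`. The number of bins is `floor(T / bin_size)`;
#' spikes beyond the last full bin are dropped.
#'
#' @param spikes a `spike_train_set`.
#' @param bin_size bin width in ms (default 25).
#' @return a `psth_matrix`: numeric matrix neurons x bins with attribute
#'   `bin_size`.
#' @export
psth <- function(spikes, bin_size = 25) {
  if (bin_size <= 0) rlang::abort("`bin_size` must be positive.")
  n <- attr(spikes, "n_neurons")
  tr <- attr(spikes, "n_trials")
  nb <- floor(attr(spikes, "duration") / bin_size)
  counts <- matrix(0, nrow = n, ncol = nb)
  df <- tibble::as_tibble(spikes)
  b <- floor(df$time / bin_size)
  ok <- b < nb
  if (any(ok)) {
    t <- table(factor(df$neuron[ok], levels = 0:(n - 1L)),
               factor(b[ok], levels = 0:(nb - 1L)))
    counts <- matrix(as.numeric(t), nrow = n, ncol = nb)
  }
  structure(counts / tr, class = "psth_matrix", bin_size = bin_size)
}

#' Normalised cross-covariance of PSTHs
#'
#' For each pair of neurons the covariance of their PSTH rows is normalised
#' by the geometric mean of the variances, `R_ij = C_ij / sqrt(C_ii C_jj)`.
#' PSTHs from different stimuli can be concatenated before the computation.
#' Rows with zero variance (non-responding neurons) are masked invalid: their
#' entries are `NA` and they are excluded from all downstream means.
#'
#' @param p a `psth_matrix`.
#' @param concatenate optional list of further `psth_matrix` objects with the
#'   same neuron set and bin size, concatenated column-wise.
#' @return a `correlation_matrix`: list with `R` (neurons x neurons, unit
#'   diagonal on valid entries) and `valid` (logical vector per neuron).
#' @export
correlation_matrix <- function(p, concatenate = NULL) {
  rates <- unclass(p)
  if (!is.null(concatenate)) {
    for (q in concatenate) {
      if (nrow(q) != nrow(rates) || !isTRUE(all.equal(attr(q, "bin_size"), attr(p, "bin_size")))) {
        rlang::abort("concatenated PSTHs must share neuron set and bin size.")
      }
      rates <- cbind(rates, unclass(q))
    }
  }
  ctr <- rates - rowMeans(rates)
  C <- tcrossprod(ctr) / (ncol(rates) - 1L)
  v <- diag(C)
  valid <- v > 0
  denom <- sqrt(outer(v, v))
  R <- C / denom
  R[!valid, ] <- NA_real_
  R[, !valid] <- NA_real_
  diag(R)[valid] <- 1
  structure(list(R = R, valid = valid), class = "correlation_matrix")
}

#' @exportS3Method base::print
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix: %d neurons, %d valid>\n",
              length(x$valid), sum(x$valid)))
  invisible(x)
}

#' Transmission-response graph time series
#'
#' Divides a single-trial recording of duration T into N = ceiling(T / dt1)
#' bins of width `dt1` ms. For bin n (0-based), the binary matrix A(n) has
#' entry (j, k) = 1 exactly when (1) the structural edge j -> k exists,
#' (2) neuron j spikes at some time s with `n*dt1 <= s < (n+1)*dt1`, and
#' (3) neuron k spikes at a time strictly inside `(s, s + dt2)` for such an
#' s. Response windows may extend past the bin boundary, so A(n) covers the
#' interval `[n*dt1, (n+1)*dt1 + dt2]`. Every A(n) is a subgraph of the
#' structural connectivity.
#'
#' @param spikes a single-trial `spike_train_set`.
#' @param structure a `directed_graph`.
#' @param dt1 bin width in ms (default 5).
#' @param dt2 transmission window in ms (default 10).
#' @return a `tr_series`: list with `active` (per bin, integer vector of
#'   active edge row indices into `structure$edges`), `n_bins`, `dt1`, `dt2`,
#'   and the `structure` edge count/vertex count.
#' @export
tr_series <- function(spikes, structure, dt1 = 5, dt2 = 10) {
  if (dt1 <= 0 || dt2 <= 0) rlang::abort("`dt1` and `dt2` must be positive.")
  if (attr(spikes, "n_trials") != 1L) {
    rlang::abort("tr_series requires a single-trial spike set (one series per trial).")
  }
  df <- tibble::as_tibble(spikes)
  n_bins <- as.integer(ceiling(attr(spikes, "duration") / dt1))
  by_neuron <- split(df$time, factor(df$neuron, levels = 0:(attr(spikes, "n_neurons") - 1L)))
  e <- structure$edges
  hits <- vector("list", nrow(e))
  for (r in seq_len(nrow(e))) {
    sj <- by_neuron[[e[r, 1] + 1L]]
    sk <- by_neuron[[e[r, 2] + 1L]]
    if (length(sj) == 0 || length(sk) == 0) next
    transmit <- vapply(sj, function(s) any(sk > s & sk < s + dt2), logical(1))
    if (any(transmit)) {
      hits[[r]] <- unique(as.integer(floor(sj[transmit] / dt1)))
    }
  }
  active <- replicate(n_bins, integer(0), simplify = FALSE)
  for (r in seq_len(nrow(e))) {
    for (b in hits[[r]]) {
      active[[b + 1L]] <- c(active[[b + 1L]], r)
    }
  }
  structure(list(active = active, n_bins = n_bins, dt1 = dt1, dt2 = dt2,
                 n_edges = nrow(e), n_vertices = structure$n_vertices),
            class = "tr_series")
}

#' @exportS3Method base::print
print.tr_series <- function(x, ...) {
  cat(sprintf("<tr_series: %d bins (dt1 = %g ms, dt2 = %g ms), %d structural edges>\n",
              x$n_bins, x$dt1, x$dt2, x$n_edges))
  invisible(x)
}

#' Extract one transmission-response matrix
#'
#' @param tr a `tr_series`.
#' @param n 0-based bin index.
#' @param structure the `directed_graph` used to build the series.
#' @return a sparse binary matrix A(n), subgraph of the structural adjacency.
#' @export
tr_matrix <- function(tr, n, structure) {
  idx <- tr$active[[n + 1L]]
  Matrix::sparseMatrix(i = structure$edges[idx, 1] + 1L,
                       j = structure$edges[idx, 2] + 1L, x = rep(1L, length(idx)),
                       dims = c(tr$n_vertices, tr$n_vertices))
}

#' Active-simplex enrichment of transmission-response graphs
#'
#' For each time bin, computes the fraction of structural edges that are
#' active and, for each requested dimension k, the fraction of structural
#' k-simplices all of whose edges are active (i.e. simplices of the TR graph
#' that are simplices of the structural graph). The same simplex fraction is
#' computed for control graphs with equally many edges drawn uniformly from
#' the structural edge set, isolating the excess of coherent simplices over
#' what edge count alone predicts.
#'
#' @param tr a `tr_series`.
#' @param structure the `directed_graph` used to build the series.
#' @param dims integer vector of simplex dimensions (default 2).
#' @param n_random number of random-edge control draws per bin (default 10).
#' @param seed integer RNG seed for the controls.
#' @param budget simplex budget for the structural flag complex.
#' @return a tibble with columns `bin`, `n_active_edges`, `edge_fraction`,
#'   `dimension`, `n_simplices_total`, `n_active_simplices`,
#'   `simplex_fraction`, `control_simplex_fraction`, `control_sd`.
#' @export
active_simplex_enrichment <- function(tr, structure, dims = 2, n_random = 10,
                                      seed = 1L, budget = 1e7) {
  dims <- sort(unique(as.integer(dims)))
  st <- flag_complex(structure, max_dim = max(dims), budget = budget)
  m <- tr$n_edges
  ekey <- edge_key(structure$edges, structure$n_vertices)
  # per dimension: matrix simplex x pair -> edge row index
  eidx <- list()
  for (k in dims) {
    if (k > st$max_dim || st$counts[k + 1L] == 0) {
      eidx[[as.character(k)]] <- matrix(integer(0), ncol = k * (k + 1) / 2)
      next
    }
    sm <- st$simplices[[k + 1L]]
    cols <- list()
    for (i in seq_len(k)) {
      for (j in (i + 1):(k + 1L)) {
        cols[[length(cols) + 1L]] <- match(edge_key(sm[, c(i, j), drop = FALSE],
                                                    structure$n_vertices), ekey)
      }
    }
    eidx[[as.character(k)]] <- do.call(cbind, cols)
  }
  frac_active <- function(active_logical, k) {
    em <- eidx[[as.character(k)]]
    if (nrow(em) == 0) return(c(0L, 0))
    n_act <- sum(rowSums(matrix(active_logical[em], nrow = nrow(em))) == ncol(em))
    c(n_act, n_act / nrow(em))
  }
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(tr$n_bins) - 1L) {
      act <- rep(FALSE, m)
      act[tr$active[[b + 1L]]] <- TRUE
      ne <- sum(act)
      for (k in dims) {
        fa <- frac_active(act, k)
        ctrl <- vapply(seq_len(n_random), function(s) {
          rnd <- rep(FALSE, m)
          rnd[sample.int(m, ne)] <- TRUE
          frac_active(rnd, k)[2]
        }, numeric(1))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          bin = b, n_active_edges = ne, edge_fraction = ne / m,
          dimension = k,
          n_simplices_total = nrow(eidx[[as.character(k)]]),
          n_active_simplices = fa[1], simplex_fraction = fa[2],
          control_simplex_fraction = mean(ctrl), control_sd = stats::sd(ctrl)
        )
      }
    }
  })
  dplyr::bind_rows(rows)
}

#' Mean pairwise correlation by per-edge maximal-simplex count
#'
#' Groups the ordered structural edges by the number of maximal simplices of
#' each dimension they belong to and reports the mean pairwise correlation of
#' the corresponding neuron pairs. Groups with fewer than `min_samples` edges
#' are omitted, as are pairs involving a masked (zero-variance) neuron.
#'
#' @param r a `correlation_matrix`.
#' @param prof a `participation_profile` over the same graph.
#' @param min_samples minimum edges per reported group (default 1000).
#' @return a tibble with columns `dimension`, `n_maximal`, `mean_r`,
#'   `n_edges`.
#' @export
edge_participation_correlation <- function(r, prof, min_samples = 1000) {
  pem <- prof$per_edge_maximal_counts
  rvals <- r$R[cbind(pem$pre + 1L, pem$post + 1L)]
  dims <- grep("^dim", names(pem), value = TRUE)
  pem |>
    dplyr::mutate(.r = rvals) |>
    tidyr::pivot_longer(dplyr::all_of(dims), names_to = "dimension",
                        names_prefix = "dim", values_to = "n_maximal") |>
    dplyr::mutate(dimension = as.integer(.data$dimension)) |>
    dplyr::filter(!is.na(.data$.r)) |>
    dplyr::group_by(.data$dimension, .data$n_maximal) |>
    dplyr::summarise(mean_r = mean(.data$.r), n_edges = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n_edges >= min_samples)
}

#' Mean pairwise correlation by position within maximal simplices
#'
#' For every maximal simplex of each dimension, three designated vertex pairs
#' are considered: the first two vertices (`first-second`), the source and
#' the sink (`source-sink`), and the last two vertices (`last-pair`). Reports
#' the mean pairwise correlation per dimension and pair kind; in dimension 1
#' all three coincide with the edge's own pair.
#'
#' @param r a `correlation_matrix`.
#' @param maximal a `simplex_table` of maximal simplices
#'   (from [maximal_simplices()]).
#' @return a tibble with columns `dimension`, `pair_kind`, `mean_r`,
#'   `n_pairs`.
#' @export
position_pair_correlation <- function(r, maximal) {
  rows <- list()
  for (d in seq_len(maximal$max_dim)) {
    m <- maximal$simplices[[d + 1L]]
    if (nrow(m) == 0) next
    pairs <- list(
      "first-second" = m[, c(1, 2), drop = FALSE],
      "source-sink" = m[, c(1, d + 1L), drop = FALSE],
      "last-pair" = m[, c(d, d + 1L), drop = FALSE]
    )
    for (kind in names(pairs)) {
      p <- pairs[[kind]]
      v <- r$R[cbind(p[, 1] + 1L, p[, 2] + 1L)]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dimension = d, pair_kind = kind,
        mean_r = if (length(v) > 0) mean(v) else NA_real_,
        n_pairs = length(v)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' PSTH bin-size sensitivity sweep
#'
#' Recomputes the PSTH and pairwise correlation matrix over a set of bin
#' sizes and reports the mean off-diagonal correlation per bin size.
#'
#' @param spikes a `spike_train_set`.
#' @param bin_sizes bin widths in ms.
#' @return a tibble with columns `bin_size`, `mean_r`, `n_valid`.
#' @export
psth_sweep <- function(spikes, bin_sizes = c(10, 25, 50, 100, 250, 500)) {
  purrr::map_dfr(bin_sizes, function(b) {
    cm <- correlation_matrix(psth(spikes, bin_size = b))
    off <- cm$R
    diag(off) <- NA
    tibble::tibble(bin_size = b, mean_r = mean(off, na.rm = TRUE),
                   n_valid = sum(cm$valid))
  })
}
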