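# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately implemented by definition (subsets,
# permutations, explicit path search), not by the package's algorithms.

# random directed graph: each ordered off-diagonal pair independently with
# probability p (reciprocal pairs allowed)
random_digraph <- function(n, p, seed) {
  withr::with_seed(seed, {
    pre <- rep(0:(n - 1L), each = n)
    post <- rep(0:(n - 1L), times = n)
    ok <- pre != post & stats::runif(n * n) < p
    directed_graph(cbind(pre[ok], post[ok]), n_vertices = n)
  })
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_permutations(v[-i]))
  }))
}

# brute-force directed flag complex: every ordered tuple over every vertex
# subset, checked against the adjacency matrix by definition
oracle_flag_complex <- function(g) {
  n <- g$n_vertices
  A <- matrix(FALSE, n, n)
  if (nrow(g$edges) > 0) A[g$edges + 1L] <- TRUE
  out <- list(matrix(0:(n - 1L), ncol = 1))
  und <- A | t(A)
  for (k in 2:n) {
    found <- list()
    subs <- utils::combn(n, k)
    for (ci in seq_len(ncol(subs))) {
      s <- subs[, ci]
      pairs <- utils::combn(s, 2)
      if (!all(und[t(pairs)])) next   # not an undirected clique: skip early
      perms <- all_permutations(s)
      for (ri in seq_len(nrow(perms))) {
        t_ <- perms[ri, ]
        ok <- TRUE
        for (i in 1:(k - 1)) {
          for (j in (i + 1):k) {
            if (!A[t_[i], t_[j]]) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) found[[length(found) + 1L]] <- t_ - 1L
      }
    }
    if (length(found) == 0) break
    out[[k]] <- do.call(rbind, found)
  }
  out
}

# sorted character keys of a simplex matrix / table dimension
keys_of <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(character(0))
  sort(apply(m, 1, paste, collapse = ","))
}

table_keys <- function(st) lapply(st$simplices, keys_of)

# cycle detection by explicit search for a closed directed walk that revisits
# its start without repeating intermediate vertices
oracle_has_cycle <- function(edges, n) {
  if (nrow(edges) == 0) return(FALSE)
  adj <- lapply(1:n, function(v) edges[edges[, 1] + 1L == v, 2] + 1L)
  visited <- integer(0)
  found <- FALSE
  dfs <- function(v, stack) {
    if (found) return()
    for (w in adj[[v]]) {
      if (w %in% stack) { found <<- TRUE; return() }
      dfs(w, c(stack, w))
    }
  }
  for (v in 1:n) { dfs(v, v); if (found) break }
  found
}

# brute-force transmission-response oracle: all (edge, pre-spike, post-spike)
# triples checked literally against the three conditions
oracle_tr <- function(spike_df, edges, n_neurons, duration, dt1, dt2) {
  n_bins <- as.integer(ceiling(duration / dt1))
  act <- replicate(n_bins, integer(0), simplify = FALSE)
  for (r in seq_len(nrow(edges))) {
    j <- edges[r, 1]; k <- edges[r, 2]
    sj <- spike_df$time[spike_df$neuron == j]
    sk <- spike_df$time[spike_df$neuron == k]
    for (n in 0:(n_bins - 1L)) {
      hit <- FALSE
      for (s in sj) {
        if (s >= n * dt1 && s < (n + 1) * dt1) {
          for (t_ in sk) {
            if (t_ - s > 0 && t_ - s < dt2) { hit <- TRUE; break }
          }
        }
        if (hit) break
      }
      if (hit) act[[n + 1L]] <- c(act[[n + 1L]], r)
    }
  }
  act
}

# acyclic tournament on n vertices under a random relabelling
shuffled_tournament <- function(n, seed) {
  withr::with_seed(seed, {
    relabel <- sample(0:(n - 1L))
    pairs <- t(utils::combn(0:(n - 1L), 2))
    directed_graph(cbind(relabel[pairs[, 1] + 1L], relabel[pairs[, 2] + 1L]),
                   n_vertices = n)
  })
}
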