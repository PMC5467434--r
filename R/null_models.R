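#' Density-matched uniform random control (ER)
#'
#' Keeps the vertex count and exact edge count of the reference graph and
#' redraws the edges uniformly without replacement from all ordered
#' off-diagonal pairs — the directed analogue of an Erdos-Renyi graph matched
#' in size and density.
#'
#' @param reference a `directed_graph`.
#' @param seed integer RNG seed (required; same seed, same graph).
#' @return a `directed_graph` with the same `n_vertices` and edge count.
#' @export
er_control <- function(reference, seed) {
  n <- reference$n_vertices
  m <- nrow(reference$edges)
  withr::with_seed(as.integer(seed), {
    total <- as.numeric(n) * (n - 1)
    pick <- sample.int(total, m)                     # ranks among ordered pairs
    pre <- (pick - 1) %/% (n - 1)                    # 0-based source
    off <- (pick - 1) %% (n - 1)                     # 0..n-2
    post <- ifelse(off >= pre, off + 1, off)         # skip the diagonal
    directed_graph(cbind(as.integer(pre), as.integer(post)), n_vertices = n,
                   positions = reference$positions, labels = reference$labels)
  })
}

#' Pruned-candidate control (PR)
#'
#' Uniformly prunes a permissive candidate graph (e.g. a structural
#' apposition graph, or any distance-threshold prior) down to a target edge
#' count, preserving the candidate's support.
#'
#' @param candidate a `directed_graph` of permitted edges.
#' @param target_edge_count number of edges to keep.
#' @param seed integer RNG seed.
#' @return a `directed_graph` whose edge set is a uniform subset of the
#'   candidate's.
#' @export
pr_control <- function(candidate, target_edge_count, seed) {
  m <- nrow(candidate$edges)
  target_edge_count <- as.integer(target_edge_count)
  if (target_edge_count > m) {
    rlang::abort("target edge count exceeds the candidate graph's edge count.")
  }
  withr::with_seed(as.integer(seed), {
    keep <- sort(sample.int(m, target_edge_count))
    directed_graph(candidate$edges[keep, , drop = FALSE],
                   n_vertices = candidate$n_vertices,
                   positions = candidate$positions, labels = candidate$labels)
  })
}

#' Distance-preserving shuffle control (GB)
#'
#' Splits the edges into blocks by (presynaptic type, postsynaptic type),
#' groups each block's connections into soma-distance bins of fixed width,
#' and resamples each connection's postsynaptic target uniformly among
#' vertices of the same postsynaptic type whose distance from the source
#' falls in the same bin. Per-block edge counts and per-block binned
#' soma-distance histograms are preserved exactly. A draw that would create a
#' self-loop or duplicate the original target is allowed to select the
#' original target; collisions with already-placed edges are resolved by
#' bounded retry, falling back to the original target (recorded in attribute
#' `"kept_original"`).
#'
#' @param reference a `directed_graph` with `positions` and `labels`.
#' @param type_col name of the label column defining vertex types
#'   (default `"mtype"`).
#' @param seed integer RNG seed.
#' @param distance_bin bin width in micrometres (default 75).
#' @param max_retries bounded retry count on duplicate collisions.
#' @return a `directed_graph`; attribute `"kept_original"` lists edge rows
#'   whose original target was retained.
#' @export
gb_control <- function(reference, type_col = "mtype", seed, distance_bin = 75,
                       max_retries = 100) {
  if (is.null(reference$positions)) rlang::abort("GB control requires vertex positions.")
  if (is.null(reference$labels) || !type_col %in% names(reference$labels)) {
    rlang::abort(sprintf("GB control requires a `%s` label column.", type_col))
  }
  if (distance_bin <= 0) rlang::abort("`distance_bin` must be positive.")
  n <- reference$n_vertices
  pos <- reference$positions
  type <- as.character(reference$labels[[type_col]])
  e <- reference$edges
  d <- sqrt(rowSums((pos[e[, 1] + 1L, , drop = FALSE] -
                     pos[e[, 2] + 1L, , drop = FALSE])^2))
  bin_of_edge <- floor(d / distance_bin)
  new_post <- e[, 2]
  kept <- integer(0)
  withr::with_seed(as.integer(seed), {
    taken <- new.env(hash = TRUE, size = nrow(e))
    blocks <- split(seq_len(nrow(e)),
                    list(pre = type[e[, 1] + 1L], post = type[e[, 2] + 1L]),
                    drop = TRUE)
    by_type <- split(0:(n - 1L), type)
    for (rows in blocks) {
      post_type <- type[e[rows[1], 2] + 1L]
      cand_all <- by_type[[post_type]]
      for (r in rows) {
        src <- e[r, 1]
        dd <- sqrt(colSums((t(pos[cand_all + 1L, , drop = FALSE]) - pos[src + 1L, ])^2))
        cand <- cand_all[floor(dd / distance_bin) == bin_of_edge[r] & cand_all != src]
        placed <- FALSE
        if (length(cand) > 0) {
          for (try in seq_len(max_retries)) {
            tgt <- cand[sample.int(length(cand), 1)]
            key <- paste0(src, "_", tgt)
            if (is.null(taken[[key]])) {
              taken[[key]] <- TRUE
              new_post[r] <- tgt
              placed <- TRUE
              break
            }
          }
        }
        if (!placed) {
          key <- paste0(src, "_", e[r, 2])
          # original target retained (no alternative, or retries exhausted)
          if (!is.null(taken[[key]])) {
            rlang::abort("GB shuffle could not place an edge without duplication.")
          }
          taken[[key]] <- TRUE
          new_post[r] <- e[r, 2]
          kept <- c(kept, r)
        }
      }
    }
  })
  out <- directed_graph(cbind(e[, 1], new_post), n_vertices = n,
                        positions = pos, labels = reference$labels)
  attr(out, "kept_original") <- kept
  if (length(kept) > 0) {
    rlang::inform(sprintf("gb_control: original target retained for %d of %d edges.",
                          length(kept), nrow(e)))
  }
  out
}
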