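#' Directed flag complex of a directed graph
#'
#' The directed flag complex has one n-simplex for every (n+1)-tuple of
#' vertices `(v0, ..., vn)` such that the graph contains the edge `vi -> vj`
#' for all `i < j`. The first vertex is the source of the simplex (edges to
#' every later vertex) and the last is the sink. Tuples with the same vertex
#' set but different orders are distinct simplices (possible only when
#' reciprocal edges exist). Enumeration proceeds by sink extension: a simplex
#' is extended by every vertex in the intersection of the out-neighbourhoods
#' of its members, generating each simplex exactly once in lexicographic
#' order.
#'
#' @param g a [directed_graph()].
#' @param max_dim optional truncation dimension; `NULL` enumerates all
#'   dimensions. Truncated tables cannot be used where maximality or the
#'   Euler characteristic is needed.
#' @param budget guard on the total number of simplices (default `1e7`);
#'   exceeding it raises an error naming the dimension reached.
#' @return a `simplex_table`: list with `simplices` (per dimension, an
#'   integer matrix of 0-based vertex tuples in lexicographic row order),
#'   `counts`, `max_dim`, `truncated`, `n_vertices`.
#' @examples
#' g <- known_complex("cycle-3")
#' simplex_counts(flag_complex(g))  # three vertices, three edges, no triangle
#' @export
flag_complex <- function(g, max_dim = NULL, budget = 1e7) {
  stopifnot(inherits(g, "directed_graph"))
  md <- if (is.null(max_dim)) -1L else as.integer(max_dim)
  higher <- .flag_complex_cpp(g$n_vertices, out_neighbours(g), md, budget)
  dim0 <- matrix(seq_len(g$n_vertices) - 1L, ncol = 1)
  simplices <- c(list(dim0), higher)
  # drop trailing empty dimensions
  nonempty <- vapply(simplices, nrow, 1L) > 0
  top <- if (any(nonempty)) max(which(nonempty)) else 1L
  simplices <- simplices[seq_len(top)]
  # conservatively flag as truncated whenever the cut could have removed
  # simplices (enumeration reached the requested ceiling)
  truncated <- !is.null(max_dim) && (length(simplices) - 1L) == as.integer(max_dim)
  new_simplex_table(simplices, n_vertices = g$n_vertices, truncated = truncated)
}

new_simplex_table <- function(simplices, n_vertices, truncated = FALSE,
                              maximal_only = FALSE) {
  counts <- vapply(simplices, nrow, 1L)
  structure(
    list(simplices = simplices,
         counts = counts,
         max_dim = length(simplices) - 1L,
         n_vertices = n_vertices,
         truncated = truncated,
         maximal_only = maximal_only),
    class = "simplex_table"
  )
}

#' @exportS3Method base::print
print.simplex_table <- function(x, ...) {
  cat(sprintf("<simplex_table: dims 0..%d%s%s>\n", x$max_dim,
              if (x$truncated) " (truncated)" else "",
              if (x$maximal_only) " (maximal only)" else ""))
  print(simplex_counts(x))
  invisible(x)
}

#' Simplex counts by dimension
#' @param st a `simplex_table`.
#' @return a tibble with columns `dimension`, `count`.
#' @export
simplex_counts <- function(st) {
  tibble::tibble(dimension = 0:st$max_dim, count = st$counts)
}

# character keys identifying simplices of one dimension
simplex_keys <- function(m) {
  if (nrow(m) == 0) return(character(0))
  do.call(paste, c(lapply(seq_len(ncol(m)), function(j) m[, j]), sep = ","))
}

#' Restrict a simplex table to its maximal simplices
#'
#' A simplex is maximal when it is a face of no other simplex. Because the
#' table is closed under faces, a simplex fails to be maximal exactly when it
#' arises from some simplex one dimension higher by deleting a single vertex
#' (insertion of a vertex at any position, not only at the sink).
#'
#' @param st a complete (untruncated) `simplex_table` from [flag_complex()].
#' @param g the source `directed_graph` (kept for interface symmetry).
#' @return a `simplex_table` containing only the maximal simplices (its
#'   per-dimension lists may be empty).
#' @export
maximal_simplices <- function(st, g = NULL) {
  if (st$truncated) {
    rlang::abort("maximality is undecidable on a truncated simplex table.")
  }
  keep <- vector("list", st$max_dim + 1L)
  for (d in 0:st$max_dim) {
    m <- st$simplices[[d + 1L]]
    is_max <- rep(TRUE, nrow(m))
    if (d < st$max_dim) {
      hi <- st$simplices[[d + 2L]]
      if (nrow(hi) > 0) {
        face_keys <- unlist(lapply(seq_len(ncol(hi)), function(j) {
          simplex_keys(hi[, -j, drop = FALSE])
        }))
        is_max <- !(simplex_keys(m) %in% face_keys)
      }
    }
    keep[[d + 1L]] <- m[is_max, , drop = FALSE]
  }
  new_simplex_table(keep, n_vertices = st$n_vertices, maximal_only = TRUE)
}

#' Closure of a set of simplices under faces
#'
#' Adds every face (vertex-subset with inherited order) of every stored
#' simplex, yielding a valid simplicial complex. The closure of the maximal
#' simplices of a flag complex reproduces the full complex.
#'
#' @param st a `simplex_table` (e.g. the output of [maximal_simplices()]).
#' @return a face-closed `simplex_table`.
#' @export
simplex_closure <- function(st) {
  out <- vector("list", st$max_dim + 1L)
  out[[st$max_dim + 1L]] <- unique_rows(st$simplices[[st$max_dim + 1L]])
  if (st$max_dim >= 1) {
    for (d in st$max_dim:1) {
      hi <- out[[d + 1L]]
      faces <- if (nrow(hi) > 0) {
        do.call(rbind, lapply(seq_len(ncol(hi)), function(j) hi[, -j, drop = FALSE]))
      } else matrix(integer(0), ncol = d)
      own <- st$simplices[[d]]
      out[[d]] <- unique_rows(rbind(own, faces))
    }
  }
  # every vertex of the source set is a 0-simplex
  verts <- sort(unique(c(out[[1]][, 1], unlist(lapply(out[-1], as.vector)))))
  out[[1]] <- matrix(verts, ncol = 1)
  new_simplex_table(lapply(out, sort_rows), n_vertices = st$n_vertices)
}

unique_rows <- function(m) {
  if (nrow(m) <= 1) return(m)
  m[!duplicated(simplex_keys(m)), , drop = FALSE]
}

sort_rows <- function(m) {
  if (nrow(m) <= 1) return(m)
  m[do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j])), , drop = FALSE]
}

#' Vertex and edge participation in simplices
#'
#' Counts, for every vertex, the number of simplices of each dimension that
#' contain it (and the highest such dimension), and for every ordered edge
#' the number of *maximal* simplices of each dimension that contain it. An
#' edge `(u, v)` is contained in a simplex when `u` precedes `v` in its
#' vertex tuple.
#'
#' @param st a complete `simplex_table` from [flag_complex()].
#' @param g the source `directed_graph`.
#' @return a `participation_profile`: list with `per_vertex_counts`
#'   (`n_vertices` x (max_dim+1) matrix), `per_vertex_maxdim`, and
#'   `per_edge_maximal_counts` (tibble `pre`, `post`, one column per
#'   dimension `dim1..`).
#' @export
participation <- function(st, g) {
  if (st$truncated) {
    rlang::abort("participation requires a complete (untruncated) table.")
  }
  nv <- st$n_vertices
  pvc <- matrix(0L, nrow = nv, ncol = st$max_dim + 1L,
                dimnames = list(NULL, paste0("dim", 0:st$max_dim)))
  for (d in 0:st$max_dim) {
    m <- st$simplices[[d + 1L]]
    if (nrow(m) > 0) pvc[, d + 1L] <- tabulate(as.vector(m) + 1L, nbins = nv)
  }
  per_vertex_maxdim <- apply(pvc > 0, 1, function(r) max(which(r)) - 1L)
  mx <- maximal_simplices(st)
  ekey <- edge_key(g$edges, nv)
  pem <- matrix(0L, nrow = nrow(g$edges), ncol = st$max_dim,
                dimnames = list(NULL, paste0("dim", seq_len(st$max_dim))))
  for (d in seq_len(st$max_dim)) {
    m <- mx$simplices[[d + 1L]]
    if (nrow(m) == 0) next
    for (i in seq_len(d)) {
      for (j in (i + 1):(d + 1L)) {
        k <- edge_key(m[, c(i, j), drop = FALSE], nv)
        t <- table(factor(match(k, ekey), levels = seq_len(nrow(g$edges))))
        pem[, d] <- pem[, d] + as.integer(t)
      }
    }
  }
  structure(
    list(per_vertex_counts = pvc,
         per_vertex_maxdim = per_vertex_maxdim,
         per_edge_maximal_counts = dplyr::bind_cols(
           tibble::tibble(pre = g$edges[, 1], post = g$edges[, 2]),
           tibble::as_tibble(pem)
         )),
    class = "participation_profile"
  )
}

#' @exportS3Method base::print
print.participation_profile <- function(x, ...) {
  cat(sprintf("<participation_profile: %d vertices, %d edges, dims 0..%d>\n",
              nrow(x$per_vertex_counts), nrow(x$per_edge_maximal_counts),
              ncol(x$per_vertex_counts) - 1L))
  invisible(x)
}

#' Simplex census of a labelled subgraph
#'
#' Builds the directed flag complex of the subgraph induced on the vertices
#' passing a predicate on the vertex labels (e.g. the excitatory subgraph, or
#' one cortical layer).
#'
#' @param g a `directed_graph` with `labels`.
#' @param vertex_filter either a logical vector over vertices, a 0-based
#'   integer id vector, or a predicate function taking the labels tibble and
#'   returning a logical vector.
#' @param max_dim,budget passed to [flag_complex()].
#' @return a `simplex_table` of the induced subgraph (vertices re-indexed;
#'   mapping in attribute `"vertex_map"`).
#' @export
subcomplex_census <- function(g, vertex_filter, max_dim = NULL, budget = 1e7) {
  if (is.function(vertex_filter)) {
    if (is.null(g$labels)) rlang::abort("graph has no vertex labels.")
    sel <- vertex_filter(g$labels)
    verts <- which(sel) - 1L
  } else if (is.logical(vertex_filter)) {
    verts <- which(vertex_filter) - 1L
  } else {
    verts <- as.integer(vertex_filter)
  }
  if (length(verts) == 0) {
    st <- new_simplex_table(list(matrix(integer(0), ncol = 1)), n_vertices = 0L)
    attr(st, "vertex_map") <- integer(0)
    return(st)
  }
  sub <- induced_subgraph(g, verts)
  st <- flag_complex(sub, max_dim = max_dim, budget = budget)
  attr(st, "vertex_map") <- attr(sub, "vertex_map")
  st
}

#' k-coskeleton of a simplicial complex
#'
#' All simplices of dimension at least `k`, together with all their faces;
#' the result is again closed under faces. Coskeleta allow the top Betti
#' numbers to be computed without carrying the full low-dimensional part of a
#' large complex.
#'
#' @param st a `simplex_table`.
#' @param k coskeleton level, `0 <= k <= max_dim` (`k = 0` is the identity).
#' @return a `simplex_table`.
#' @export
coskeleton <- function(st, k) {
  k <- as.integer(k)
  if (k < 0 || k > st$max_dim) rlang::abort("`k` must lie in [0, max_dim].")
  if (k == 0) return(st)
  kept <- vector("list", st$max_dim + 1L)
  for (d in 0:st$max_dim) {
    kept[[d + 1L]] <- if (d >= k) st$simplices[[d + 1L]]
      else matrix(integer(0), ncol = d + 1L)
  }
  # close downward: codimension-1 faces suffice for full face closure
  for (d in seq(st$max_dim, 1)) {
    hi <- kept[[d + 1L]]
    if (nrow(hi) == 0) next
    faces <- do.call(rbind, lapply(seq_len(ncol(hi)), function(j) {
      hi[, -j, drop = FALSE]
    }))
    kept[[d]] <- unique_rows(rbind(kept[[d]], faces))
  }
  nonempty <- vapply(kept, nrow, 1L) > 0
  top <- if (any(nonempty)) max(which(nonempty)) else 1L
  new_simplex_table(lapply(kept[seq_len(top)], sort_rows),
                    n_vertices = st$n_vertices)
}

# TRUE when every codimension-1 face of every simplex is stored
is_face_closed <- function(st) {
  for (d in seq_len(st$max_dim)) {
    hi <- st$simplices[[d + 1L]]
    if (nrow(hi) == 0) next
    lo_keys <- simplex_keys(st$simplices[[d]])
    for (j in seq_len(ncol(hi))) {
      if (!all(simplex_keys(hi[, -j, drop = FALSE]) %in% lo_keys)) return(FALSE)
    }
  }
  TRUE
}
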