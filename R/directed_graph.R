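#' Construct a directed graph
#'
#' A `directed_graph` is the basic container of the package: a finite set of
#' vertices `0, ..., n-1` and a set of ordered edges (source, target), the
#' convention being that the source is the presynaptic vertex. Self-loops and
#' duplicate ordered pairs are forbidden; reciprocal pairs (`u -> v` together
#' with `v -> u`) are allowed. Optional per-vertex metadata carries 3-D soma
#' positions (micrometres) and categorical labels (layer, morphological type,
#' excitatory/inhibitory class).
#'
#' @param edges a two-column integer matrix or data frame of 0-based
#'   (source, target) pairs; may have zero rows.
#' @param n_vertices number of vertices; defaults to `max(edges) + 1`.
#' @param positions optional numeric matrix (`n_vertices` x 3) of soma
#'   positions in micrometres.
#' @param labels optional data frame with `n_vertices` rows of per-vertex
#'   categorical labels (e.g. columns `layer`, `mtype`, `synapse_class`).
#' @return an object of class `directed_graph`.
#' @examples
#' g <- directed_graph(rbind(c(0, 1), c(1, 2)))
#' n_edges(g)
#' @export
directed_graph <- function(edges, n_vertices = NULL, positions = NULL,
                           labels = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
  }
  if (!is.matrix(edges) || ncol(edges) != 2) {
    rlang::abort("`edges` must be a two-column matrix of (source, target) pairs.")
  }
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) rlang::abort("`edges` contains missing or non-integer ids.")
  if (is.null(n_vertices)) {
    n_vertices <- if (nrow(edges) == 0L) 0L else max(edges) + 1L
  }
  n_vertices <- as.integer(n_vertices)
  g <- structure(
    list(n_vertices = n_vertices, edges = edges,
         positions = positions, labels = labels),
    class = "directed_graph"
  )
  validate_directed_graph(g)
}

validate_directed_graph <- function(g) {
  e <- g$edges
  if (nrow(e) > 0) {
    if (min(e) < 0 || max(e) >= g$n_vertices) {
      rlang::abort("edge endpoint out of range [0, n_vertices).")
    }
    loops <- which(e[, 1] == e[, 2])
    if (length(loops) > 0) {
      rlang::abort(sprintf("self-loop at vertex %d (edge row %d).",
                           e[loops[1], 1], loops[1]))
    }
    key <- edge_key(e)
    dup <- which(duplicated(key))
    if (length(dup) > 0) {
      rlang::abort(sprintf("duplicate ordered pair (%d, %d) (edge row %d).",
                           e[dup[1], 1], e[dup[1], 2], dup[1]))
    }
  }
  if (!is.null(g$positions)) {
    p <- as.matrix(g$positions)
    if (nrow(p) != g$n_vertices || ncol(p) != 3) {
      rlang::abort("`positions` must be an n_vertices x 3 matrix.")
    }
    g$positions <- p
  }
  if (!is.null(g$labels)) {
    if (nrow(g$labels) != g$n_vertices) {
      rlang::abort("`labels` must have one row per vertex.")
    }
    g$labels <- tibble::as_tibble(g$labels)
  }
  g
}

# unique key per ordered pair; n may exceed 2^15 so use character only when
# numeric keys could overflow doubles (they cannot for n < 9e7)
edge_key <- function(e, n = NULL) {
  if (nrow(e) == 0) return(numeric(0))
  w <- if (is.null(n)) max(e) + 1 else n
  as.numeric(e[, 1]) * w + as.numeric(e[, 2])
}

#' @exportS3Method base::print
print.directed_graph <- function(x, ...) {
  cat(sprintf("<directed_graph: %d vertices, %d edges%s%s>\n",
              x$n_vertices, nrow(x$edges),
              if (!is.null(x$positions)) ", positions" else "",
              if (!is.null(x$labels)) ", labels" else ""))
  invisible(x)
}

#' Number of vertices / edges of a directed graph
#' @param g a `directed_graph`.
#' @return an integer count.
#' @export
n_vertices <- function(g) g$n_vertices

#' @rdname n_vertices
#' @export
n_edges <- function(g) nrow(g$edges)

#' @export
as_tibble.directed_graph <- function(x, ...) {
  tibble::tibble(pre = x$edges[, 1], post = x$edges[, 2])
}

#' Read a directed graph from disk
#'
#' Supports two plain-text formats: an edge-list CSV with two integer columns
#' `pre,post` (0-based vertex ids, header optional) and Matrix Market
#' coordinate format (`.mtx`, pattern or integer field, 1-based per the
#' standard, converted to 0-based internally). In both, rows index the
#' presynaptic (source) neuron and columns the postsynaptic (target) neuron.
#'
#' @param path file to read.
#' @param format one of `"auto"` (by extension), `"edge-list-csv"`,
#'   `"matrix-market"`.
#' @param n_vertices optional vertex count override (CSV input only).
#' @return a [directed_graph()].
#' @export
read_graph <- function(path, format = c("auto", "edge-list-csv", "matrix-market"),
                       n_vertices = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE))
      "matrix-market" else "edge-list-csv"
  }
  if (format == "matrix-market") {
    m <- methods::as(Matrix::readMM(path), "TsparseMatrix")
    if (nrow(m) != ncol(m)) rlang::abort("adjacency matrix must be square.")
    e <- cbind(m@i, m@j)  # already 0-based in Tsparse slots
    key <- edge_key(e, nrow(m))
    if (anyDuplicated(key)) {
      d <- e[which(duplicated(key))[1], ]
      rlang::abort(sprintf("duplicate ordered pair (%d, %d) in %s.",
                           d[1], d[2], path))
    }
    loops <- which(e[, 1] == e[, 2])
    if (length(loops) > 0) {
      rlang::abort(sprintf("self-loop at vertex %d in %s.", e[loops[1], 1], path))
    }
    return(directed_graph(e, n_vertices = nrow(m)))
  }
  raw <- readr::read_csv(path, col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  offset <- 0L
  if (nrow(raw) > 0 && any(is.na(suppressWarnings(as.integer(unlist(raw[1, 1:2])))))) {
    raw <- raw[-1, , drop = FALSE]  # header line
    offset <- 1L
  }
  if (nrow(raw) == 0) return(directed_graph(NULL, n_vertices = n_vertices %||% 0L))
  pre <- suppressWarnings(as.numeric(raw[[1]]))
  post <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(pre) | is.na(post) | pre != floor(pre) | post != floor(post))
  if (length(bad) > 0) {
    rlang::abort(sprintf("non-integer vertex id on line %d of %s.",
                         bad[1] + offset, path))
  }
  e <- cbind(as.integer(pre), as.integer(post))
  loops <- which(e[, 1] == e[, 2])
  if (length(loops) > 0) {
    rlang::abort(sprintf("self-loop on line %d of %s.", loops[1] + offset, path))
  }
  dup <- which(duplicated(edge_key(e)))
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate ordered pair on line %d of %s.",
                         dup[1] + offset, path))
  }
  directed_graph(e, n_vertices = n_vertices)
}

#' Write a directed graph to disk
#'
#' Inverse of [read_graph()]; `read_graph(write_graph(g, path))` reproduces
#' the edge set exactly.
#'
#' @param g a `directed_graph`.
#' @param path output file.
#' @param format `"edge-list-csv"` or `"matrix-market"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("auto", "edge-list-csv", "matrix-market")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE))
      "matrix-market" else "edge-list-csv"
  }
  if (format == "matrix-market") {
    m <- adjacency_sparse(g)
    Matrix::writeMM(m, path)
  } else {
    readr::write_csv(tibble::tibble(pre = g$edges[, 1], post = g$edges[, 2]), path)
  }
  invisible(path)
}

#' Sparse adjacency matrix of a directed graph
#'
#' Rows index presynaptic (source) vertices, columns postsynaptic (target).
#' @param g a `directed_graph`.
#' @return a sparse pattern matrix (`Matrix::ngCMatrix`-like).
#' @export
adjacency_sparse <- function(g) {
  Matrix::sparseMatrix(i = g$edges[, 1] + 1L, j = g$edges[, 2] + 1L,
                       x = rep(1L, nrow(g$edges)),
                       dims = c(g$n_vertices, g$n_vertices))
}

adjacency_logical <- function(g) {
  a <- matrix(FALSE, g$n_vertices, g$n_vertices)
  if (nrow(g$edges) > 0) a[g$edges + 1L] <- TRUE
  a
}

# sorted 0-based out-neighbour lists
out_neighbours <- function(g) {
  out <- vector("list", g$n_vertices)
  if (nrow(g$edges) > 0) {
    sp <- split(g$edges[, 2], factor(g$edges[, 1], levels = 0:(g$n_vertices - 1L)))
    out <- lapply(sp, function(v) sort(as.integer(v)))
  } else if (g$n_vertices > 0) {
    out <- replicate(g$n_vertices, integer(0), simplify = FALSE)
  }
  out
}

# igraph construction that always carries isolated vertices
to_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_vertices, directed = TRUE)
  if (nrow(g$edges) > 0) ig <- igraph::add_edges(ig, t(g$edges + 1L))
  ig
}

#' Signed degree of vertices
#'
#' The signed degree of a vertex is its in-degree minus its out-degree. Over
#' any finite directed graph the signed degrees sum to zero.
#'
#' @param g a `directed_graph`.
#' @param v optional single 0-based vertex id; if omitted, all vertices.
#' @return an integer scalar (if `v` given) or the full integer vector
#'   indexed by vertex `0..n-1`.
#' @export
signed_degree <- function(g, v = NULL) {
  indeg <- tabulate(g$edges[, 2] + 1L, nbins = g$n_vertices)
  outdeg <- tabulate(g$edges[, 1] + 1L, nbins = g$n_vertices)
  sd <- as.integer(indeg - outdeg)
  if (is.null(v)) return(sd)
  if (length(v) != 1 || v < 0 || v >= g$n_vertices) {
    rlang::abort(sprintf("vertex %s out of range [0, %d).", toString(v), g$n_vertices))
  }
  sd[v + 1L]
}

#' Net directionality of a directed graph
#'
#' The sum over all vertices of the squared signed degree,
#' `Dr(G) = sum_v sd(v)^2`. Among fully connected unidirectional graphs on
#' `n + 1` vertices this is maximised exactly by the directed n-simplex.
#'
#' @param g a `directed_graph`.
#' @return a non-negative integer.
#' @export
directionality <- function(g) {
  sum(as.numeric(signed_degree(g))^2)
}

#' Test a directed graph for acyclicity
#'
#' A graph is acyclic when it contains no oriented cycle. A reciprocal pair
#' (`u -> v` and `v -> u`) is an oriented cycle of length 2, so any graph
#' containing one is cyclic.
#'
#' @param g a `directed_graph`.
#' @return `TRUE` or `FALSE`.
#' @export
is_acyclic <- function(g) {
  if (nrow(g$edges) == 0) return(TRUE)
  igraph::is_dag(to_igraph(g))
}

#' Weakly connected components
#'
#' Components of the underlying undirected graph.
#'
#' @param g a `directed_graph`.
#' @return an integer vector of component memberships (1-based component
#'   ids), one per vertex, with attribute `"n_components"`.
#' @export
weakly_connected_components <- function(g) {
  if (g$n_vertices == 0) {
    return(structure(integer(0), n_components = 0L))
  }
  comp <- igraph::components(to_igraph(g), mode = "weak")
  structure(as.integer(comp$membership), n_components = comp$no)
}

#' Census of fully connected directed configurations
#'
#' On `k` labeled vertices with every unordered pair connected, each of the
#' `k(k-1)/2` pairs can be in one of three states (one direction, the other,
#' or reciprocal), giving `3^(k(k-1)/2)` configurations. Restricting to
#' unidirectional configurations (tournaments) gives `2^(k(k-1)/2)`, which
#' split into acyclic ones — the directed (k-1)-simplices — and those
#' containing an oriented cycle. Acyclicity is decided by exhaustive
#' enumeration of all tournaments; configurations are counted on labeled
#' vertices with no isomorphism quotient.
#'
#' @param k number of vertices (2 to 5; the state space is `3^(k(k-1)/2)`).
#' @return a one-row tibble with columns `n_total_configurations`,
#'   `n_unidirectional`, `n_acyclic`, `n_cyclic`.
#' @examples
#' motif_census(4)  # 729 total, 64 unidirectional, 24 acyclic, 40 cyclic
#' @export
motif_census <- function(k) {
  k <- as.integer(k)
  if (k < 2 || k > 5) {
    rlang::abort("`k` must be between 2 and 5 (exhaustive enumeration guard).")
  }
  pairs <- t(utils::combn(k, 2))      # 1-based unordered pairs
  m <- nrow(pairs)
  n_acyclic <- 0L
  # enumerate all 2^m orientations of the m pairs
  for (code in 0:(2^m - 1)) {
    bits <- bitwAnd(bitwShiftR(code, 0:(m - 1)), 1L)
    src <- ifelse(bits == 1L, pairs[, 2], pairs[, 1])
    dst <- ifelse(bits == 1L, pairs[, 1], pairs[, 2])
    if (!has_cycle_edges(cbind(src, dst), k)) n_acyclic <- n_acyclic + 1L
  }
  tibble::tibble(
    n_total_configurations = as.integer(3^m),
    n_unidirectional = as.integer(2^m),
    n_acyclic = n_acyclic,
    n_cyclic = as.integer(2^m - n_acyclic)
  )
}

# Kahn's algorithm on a small 1-based edge matrix
has_cycle_edges <- function(e, n) {
  indeg <- tabulate(e[, 2], nbins = n)
  active <- rep(TRUE, n)
  repeat {
    z <- which(active & indeg == 0L)
    if (length(z) == 0) break
    active[z] <- FALSE
    keep <- !(e[, 1] %in% z)
    if (!all(keep)) {
      indeg <- indeg - tabulate(e[!keep, 2], nbins = n)
      e <- e[keep, , drop = FALSE]
    }
  }
  any(active)
}

#' Induced subgraph on a vertex subset
#'
#' Vertices are re-indexed densely (0-based) in increasing order of their
#' original id; the mapping is returned in attribute `"vertex_map"` (original
#' ids, position = new id + 1). Positions and labels are carried over.
#'
#' @param g a `directed_graph`.
#' @param vertices 0-based vertex ids to keep.
#' @return a `directed_graph`.
#' @export
induced_subgraph <- function(g, vertices) {
  vertices <- sort(unique(as.integer(vertices)))
  idx <- rep(NA_integer_, g$n_vertices)
  idx[vertices + 1L] <- seq_along(vertices) - 1L
  keep <- !is.na(idx[g$edges[, 1] + 1L]) & !is.na(idx[g$edges[, 2] + 1L])
  e <- cbind(idx[g$edges[keep, 1] + 1L], idx[g$edges[keep, 2] + 1L])
  sub <- directed_graph(
    e, n_vertices = length(vertices),
    positions = if (!is.null(g$positions)) g$positions[vertices + 1L, , drop = FALSE],
    labels = if (!is.null(g$labels)) g$labels[vertices + 1L, , drop = FALSE]
  )
  attr(sub, "vertex_map") <- vertices
  sub
}

#' Disjoint union of directed graphs
#'
#' Vertices of `h` are shifted by `n_vertices(g)`.
#' @param g,h `directed_graph` objects.
#' @return a `directed_graph`.
#' @export
disjoint_union <- function(g, h) {
  directed_graph(rbind(g$edges, h$edges + g$n_vertices),
                 n_vertices = g$n_vertices + h$n_vertices)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
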