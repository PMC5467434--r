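#' Boundary matrices of a simplicial complex over GF(2)
#'
#' For each dimension n >= 1, the differential maps an n-simplex to the sum
#' of its n+1 faces (the i-th face deletes the vertex at position n - i);
#' over the two-element field no orientation signs are needed. The matrix
#' `D_n` has shape |S_{n-1}| x |S_n| with entry (tau, sigma) = 1 exactly when
#' tau is a face of sigma obtained by deleting one vertex. Simplices are
#' indexed in lexicographic order of their vertex tuples, so the matrices are
#' reproducible.
#'
#' @param st a face-closed `simplex_table`.
#' @return a `chain_complex_gf2`: list with `boundary` (list of
#'   `Matrix::sparseMatrix` objects, `boundary[[n]]` = D_n), `counts`, and
#'   `basis` (the per-dimension simplex matrices defining row/column order).
#' @export
boundary_matrices <- function(st) {
  if (!is_face_closed(st)) {
    rlang::abort("simplex table is not closed under faces; cannot form a chain complex.")
  }
  basis <- lapply(st$simplices, sort_rows)
  boundary <- vector("list", st$max_dim)
  for (n in seq_len(st$max_dim)) {
    hi <- basis[[n + 1L]]
    lo_keys <- simplex_keys(basis[[n]])
    if (nrow(hi) == 0) {
      boundary[[n]] <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = integer(0),
                                            dims = c(nrow(basis[[n]]), 0))
      next
    }
    ii <- jj <- vector("list", ncol(hi))
    for (f in seq_len(ncol(hi))) {
      rows <- match(simplex_keys(hi[, -f, drop = FALSE]), lo_keys)
      ii[[f]] <- rows
      jj[[f]] <- seq_len(nrow(hi))
    }
    boundary[[n]] <- Matrix::sparseMatrix(
      i = unlist(ii), j = unlist(jj), x = 1L,
      dims = c(nrow(basis[[n]]), nrow(hi))
    )
  }
  structure(
    list(boundary = boundary,
         counts = vapply(basis, nrow, 1L),
         basis = basis,
         truncated = st$truncated),
    class = "chain_complex_gf2"
  )
}

#' @exportS3Method base::print
print.chain_complex_gf2 <- function(x, ...) {
  cat(sprintf("<chain_complex_gf2: C0..C%d with counts %s>\n",
              length(x$counts) - 1L, paste(x$counts, collapse = ", ")))
  invisible(x)
}

gf2_rank <- function(D) {
  if (is.null(D) || any(dim(D) == 0)) return(0L)
  t <- methods::as(D, "TsparseMatrix")
  # entries are 0/1; drop even duplicates defensively
  .gf2_rank_cpp(t@i, t@j, nrow(D), ncol(D))
}

#' Mod-2 Betti numbers
#'
#' Betti numbers are computed from ranks and nullities of the boundary
#' matrices over the two-element field: `beta_0 = |S_0| - rk(D_1)`,
#' `beta_n = null(D_n) - rk(D_{n+1})` for intermediate n, and
#' `beta_top = null(D_top)`. The n-th Betti number counts the n-dimensional
#' cavities of the geometric realization.
#'
#' @param x a `chain_complex_gf2` or a face-closed `simplex_table` (the chain
#'   complex is built on the fly).
#' @return a `betti_profile`: list with `betti` (integer vector, entry n+1 is
#'   beta_n), `euler_characteristic`, and `computed_dims`. For a truncated
#'   table, dimensions whose neighbourhood is incomplete are `NA` and the
#'   Euler characteristic is `NA`.
#' @examples
#' betti_numbers(flag_complex(known_complex("octahedron-sphere")))
#' @export
betti_numbers <- function(x) {
  cc <- if (inherits(x, "chain_complex_gf2")) x else boundary_matrices(x)
  top <- length(cc$counts) - 1L
  ranks <- vapply(cc$boundary, gf2_rank, 0L)       # rk(D_1) ... rk(D_top)
  betti <- rep(NA_integer_, top + 1L)
  if (top == 0L) {
    betti[1] <- cc$counts[1]
  } else {
    betti[1] <- cc$counts[1] - ranks[1]
    if (top >= 2) {
      for (n in 1:(top - 1L)) {
        betti[n + 1L] <- (cc$counts[n + 1L] - ranks[n]) - ranks[n + 1L]
      }
    }
    betti[top + 1L] <- cc$counts[top + 1L] - ranks[top]
  }
  computed <- 0:top
  if (isTRUE(cc$truncated)) {
    # the top dimension may be missing cofaces; its Betti number (and any
    # quantity needing D_{top+1}) is unavailable
    betti[top + 1L] <- NA_integer_
    computed <- computed[-(top + 1L)]
  }
  chi <- if (isTRUE(cc$truncated)) NA_integer_ else
    as.integer(sum((-1)^(0:top) * cc$counts))
  structure(
    list(betti = betti, euler_characteristic = chi, computed_dims = computed),
    class = "betti_profile"
  )
}

#' @exportS3Method base::print
print.betti_profile <- function(x, ...) {
  cat(sprintf("<betti_profile: beta = (%s), chi = %s>\n",
              paste(x$betti, collapse = ", "), x$euler_characteristic))
  invisible(x)
}

#' Euler characteristic of a simplicial complex
#'
#' The alternating sum of the simplex counts over all dimensions. It equals
#' the alternating sum of the Betti numbers.
#'
#' @param st a complete (untruncated) `simplex_table`.
#' @return an integer.
#' @export
euler_characteristic <- function(st) {
  if (st$truncated) {
    rlang::abort("Euler characteristic requires the complete simplex table.")
  }
  as.integer(sum((-1)^(0:st$max_dim) * st$counts))
}

#' Top Betti numbers via the coskeleton
#'
#' Computes `beta_k` on the k-coskeleton of the complex. The coskeleton
#' contains every simplex of dimension k and k+1 and all faces needed to
#' define the differentials, so for k >= 1 the value agrees with the Betti
#' number of the full complex while avoiding its (possibly enormous)
#' low-dimensional part.
#'
#' @param st a `simplex_table`.
#' @param k dimension (k >= 1).
#' @return the integer `beta_k`.
#' @export
top_betti_via_coskeleton <- function(st, k) {
  k <- as.integer(k)
  if (k < 1) rlang::abort("`k` must be >= 1.")
  if (k > st$max_dim) return(0L)
  cs <- coskeleton(st, k)
  cc <- boundary_matrices(cs)
  top <- length(cc$counts) - 1L
  rk_k <- gf2_rank(cc$boundary[[k]])
  rk_k1 <- if (k + 1L <= top) gf2_rank(cc$boundary[[k + 1L]]) else 0L
  as.integer((cc$counts[k + 1L] - rk_k) - rk_k1)
}

#' Serialize a Betti profile to JSON
#'
#' @param bp a `betti_profile`.
#' @param path optional output file; if `NULL`, the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
write_betti_json <- function(bp, path = NULL) {
  obj <- list(betti = bp$betti, chi = bp$euler_characteristic,
              computed_dims = bp$computed_dims)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
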