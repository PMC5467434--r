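#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simplex table
#'
#' @param x a `simplex_table`.
#' @param ... unused.
#' @return a tibble with columns `dimension`, `count`.
#' @export
tidy.simplex_table <- function(x, ...) simplex_counts(x)

#' @rdname tidy.simplex_table
#' @export
glance.simplex_table <- function(x, ...) {
  tibble::tibble(max_dim = x$max_dim,
                 n_simplices = sum(x$counts),
                 truncated = x$truncated,
                 maximal_only = x$maximal_only)
}

#' Tidy a Betti profile
#'
#' @param x a `betti_profile`.
#' @param ... unused.
#' @return a tibble with columns `dimension`, `betti`.
#' @export
tidy.betti_profile <- function(x, ...) {
  tibble::tibble(dimension = seq_along(x$betti) - 1L, betti = x$betti)
}

#' @rdname tidy.betti_profile
#' @export
glance.betti_profile <- function(x, ...) {
  b <- x$betti
  nz <- which(!is.na(b) & b > 0)
  tibble::tibble(euler_characteristic = x$euler_characteristic,
                 top_nonzero_betti = if (length(nz)) max(nz) - 1L else NA_integer_,
                 n_computed_dims = length(x$computed_dims))
}

#' Tidy a participation profile
#'
#' @param x a `participation_profile`.
#' @param ... unused.
#' @return a long tibble with columns `vertex`, `dimension`, `count`.
#' @export
tidy.participation_profile <- function(x, ...) {
  m <- x$per_vertex_counts
  tibble::as_tibble(m) |>
    dplyr::mutate(vertex = seq_len(nrow(m)) - 1L) |>
    tidyr::pivot_longer(dplyr::starts_with("dim"), names_to = "dimension",
                        names_prefix = "dim", values_to = "count") |>
    dplyr::mutate(dimension = as.integer(.data$dimension)) |>
    dplyr::select("vertex", "dimension", "count")
}

#' Tidy a correlation matrix
#'
#' @param x a `correlation_matrix`.
#' @param ... unused.
#' @return a long tibble of valid ordered pairs, columns `i`, `j`, `r`.
#' @export
tidy.correlation_matrix <- function(x, ...) {
  n <- length(x$valid)
  idx <- which(!is.na(x$R) & row(x$R) != col(x$R), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1] - 1L, j = idx[, 2] - 1L, r = x$R[idx])
}
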