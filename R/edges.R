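#' Edge-space indexing for a symmetric connectome
#'
#' The whole-brain connectome of `n_nodes` parcels has
#' `E = n_nodes * (n_nodes - 1) / 2` unique edges (6670 for the AAL-116
#' atlas). Throughout the package edges are stored as a length-`E` vector in
#' a fixed canonical order: row-major over the strict upper triangle with
#' 0-based node indices, i.e. (0,1), (0,2), ..., (0,n-1), (1,2), ...,
#' (n-2,n-1). This ordering is used by every file, mask and report.
#'
#' @param n_nodes number of parcels (nodes).
#' @return `edge_index_table()`: a data.frame with columns `edge` (0-based
#'   edge index), `node1`, `node2` (0-based node indices, `node1 < node2`).
#'   `edge_ids()`: a character vector of `"i_j"` labels in the same order.
#' @examples
#' edge_index_table(4)
#' edge_ids(3)
#' @export
edge_index_table <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 2)
  i <- rep.int(0:(n_nodes - 2L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(0:(n_nodes - 2L), function(a) (a + 1L):(n_nodes - 1L)),
              use.names = FALSE)
  data.frame(edge = seq_along(i) - 1L, node1 = i, node2 = j)
}

#' @rdname edge_index_table
#' @export
edge_ids <- function(n_nodes) {
  tab <- edge_index_table(n_nodes)
  paste0(tab$node1, "_", tab$node2)
}

#' @rdname edge_index_table
#' @export
n_edges <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  (n_nodes * (n_nodes - 1L)) %/% 2L
}

#' Vectorize a connectivity matrix into the canonical edge order
#'
#' Extracts the strict upper triangle of a symmetric connectivity matrix in
#' row-major order (see [edge_index_table()]). [unvectorize_upper()] is the
#' exact inverse; the round trip preserves every off-diagonal value.
#'
#' @param mat a symmetric numeric matrix (node x node connectivity).
#' @param tol maximum tolerated absolute asymmetry, default `1e-8`.
#' @return a numeric vector of length `n_nodes * (n_nodes - 1) / 2`.
#' @export
vectorize_upper <- function(mat, tol = 1e-8) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  asym <- max(abs(mat - t(mat)))
  if (asym > tol) {
    stop("matrix is asymmetric beyond tolerance (max |m - t(m)| = ",
         format(asym), ")")
  }
  # lower.tri of t(mat) in column-major order == upper triangle row-major
  tm <- t(mat)
  tm[lower.tri(tm)]
}

#' @rdname vectorize_upper
#' @param values a length-E edge vector in canonical order.
#' @param diag_value value placed on the diagonal (1 for correlations).
#' @export
unvectorize_upper <- function(values, diag_value = 1) {
  e <- length(values)
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(n - round(n)) > 1e-8) {
    stop("length ", e, " is not a valid edge count n*(n-1)/2")
  }
  n <- as.integer(round(n))
  tm <- matrix(0, n, n)
  tm[lower.tri(tm)] <- values
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}
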