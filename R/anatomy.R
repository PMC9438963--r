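#' The packaged AAL-116 node table
#'
#' Node labels for the 116-parcel automated anatomical labelling atlas in
#' its standard ordering: cerebral regions at 0-based indices 0-89,
#' cerebellar hemispheres 90-107, vermis 108-115. Region names and
#' abbreviations follow the atlas's canonical spelling (including
#' "Cerebelum"). The table is a plain CSV under `extdata/` and can be
#' replaced by any user table with the same columns for other atlases.
#'
#' @param path optional path to an alternative node table CSV with columns
#'   `node_index` (0-based, contiguous), `aal_name`, `abbreviation`,
#'   `hemisphere`.
#' @return a data.frame with one row per node.
#' @export
aal116_nodes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal116_nodes.csv", package = "cpmpred",
                        mustWork = TRUE)
  }
  nodes <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("node_index", "aal_name", "abbreviation", "hemisphere")
  if (!all(req %in% names(nodes))) {
    stop("node table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(nodes$node_index) ||
      !identical(sort(nodes$node_index), seq_len(nrow(nodes)) - 1L)) {
    stop("node_index must be unique, contiguous and 0-based")
  }
  nodes[order(nodes$node_index), , drop = FALSE]
}

#' Consensus edges across cross-validation folds
#'
#' Different folds may select different edges; the reported functional
#' anatomy is the set of edges selected in every fold (elementwise AND of
#' the fold masks), per network sign. Adding a fold can only shrink the
#' consensus.
#'
#' @param fold_masks list of `"selection_masks"` (one per fold), e.g.
#'   `fit$fold_masks` from [loocv_predict()].
#' @return list with logical length-E `positive` and `negative` consensus
#'   masks, plus `mean_rho` (per-edge mean over folds of the selection
#'   partial Spearman rho).
#' @export
consensus_edges <- function(fold_masks) {
  stopifnot(length(fold_masks) >= 1)
  e <- length(fold_masks[[1]]$positive_mask)
  pos <- rep(TRUE, e)
  neg <- rep(TRUE, e)
  rho_sum <- numeric(e)
  for (m in fold_masks) {
    if (length(m$positive_mask) != e || length(m$negative_mask) != e) {
      stop("inconsistent edge count across folds")
    }
    pos <- pos & m$positive_mask
    neg <- neg & m$negative_mask
    rho_sum <- rho_sum + m$rho
  }
  list(positive = pos, negative = neg,
       mean_rho = rho_sum / length(fold_masks))
}

#' Label the edges of a mask with atlas region names
#'
#' Converts a length-E boolean edge mask through the canonical edge-index
#' bijection into a table of labelled node pairs (node1 index < node2
#' index), one row per set edge.
#'
#' @param mask logical length-E edge mask.
#' @param nodes a node table (default the packaged AAL-116 table); must
#'   cover the implied node count.
#' @param mean_rho optional per-edge numeric (e.g. from
#'   [consensus_edges()]) reported as `mean_selection_rho`.
#' @return a data.frame with columns `edge` (0-based edge index), `node1`,
#'   `node2` (0-based node indices), `node1_name`, `node2_name`,
#'   `node1_abbrev`, `node2_abbrev`, and optionally `mean_selection_rho`;
#'   zero rows for an empty mask.
#' @export
label_edges <- function(mask, nodes = aal116_nodes(), mean_rho = NULL) {
  e <- length(mask)
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(n - round(n)) > 1e-8) stop("mask length is not a valid edge count")
  n <- as.integer(round(n))
  if (n > nrow(nodes)) {
    stop("mask implies ", n, " nodes but the node table has only ",
         nrow(nodes), " rows")
  }
  tab <- edge_index_table(n)
  sel <- tab[mask, , drop = FALSE]
  out <- data.frame(
    edge = sel$edge,
    node1 = sel$node1,
    node2 = sel$node2,
    node1_name = nodes$aal_name[sel$node1 + 1L],
    node2_name = nodes$aal_name[sel$node2 + 1L],
    node1_abbrev = nodes$abbreviation[sel$node1 + 1L],
    node2_abbrev = nodes$abbreviation[sel$node2 + 1L],
    stringsAsFactors = FALSE
  )
  if (!is.null(mean_rho)) {
    stopifnot(length(mean_rho) == e)
    out$mean_selection_rho <- mean_rho[mask]
  }
  rownames(out) <- NULL
  out
}

#' Render a labelled consensus edge list in report form
#'
#' Formats a [label_edges()] table in the conventional four-column layout
#' (Node 1, Node 2, abbreviations); an empty edge list renders as a single
#' em-dash row, the standard convention for "no connectivity identified".
#'
#' @param edge_list data.frame from [label_edges()].
#' @return a data.frame with columns `node1_name`, `node2_name`,
#'   `node1_abbrev`, `node2_abbrev`.
#' @export
format_edge_table <- function(edge_list) {
  cols <- c("node1_name", "node2_name", "node1_abbrev", "node2_abbrev")
  if (nrow(edge_list) == 0) {
    out <- as.data.frame(as.list(stats::setNames(rep("—", 4), cols)),
                         stringsAsFactors = FALSE)
    names(out) <- cols
    return(out)
  }
  edge_list[, cols, drop = FALSE]
}

# Inverse of label_edges: rebuild the boolean mask from 0-based edge
# indices.
mask_from_edges <- function(edge_indices, n_nodes) {
  e <- n_edges(n_nodes)
  if (any(edge_indices < 0) || any(edge_indices >= e)) {
    stop("edge index out of range for ", n_nodes, " nodes")
  }
  mask <- rep(FALSE, e)
  mask[edge_indices + 1L] <- TRUE
  mask
}
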