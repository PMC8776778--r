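#' Construct a directed network object
#'
#' @param adjacency square 0/1 matrix with isolate ids as dimnames; entry
#'   `[i, j] = 1` means an edge i -> j (i's niche significantly overlaps j's).
#' @param kingdom named character vector of kingdom labels, or unnamed in
#'   node order.
#' @param leaf_id,treatment,threshold provenance metadata.
#' @return object of class `directed_network`.
#' @export
directed_network <- function(adjacency, kingdom = NULL, leaf_id = NA_character_,
                             treatment = NA_character_, threshold = NA_real_) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  storage.mode(adjacency) <- "integer"
  if (any(is.na(adjacency)) || any(!adjacency %in% c(0L, 1L)))
    stop("adjacency entries must be 0/1")
  if (any(diag(adjacency) != 0L)) stop("self-loops are not allowed")
  if (is.null(rownames(adjacency)))
    rownames(adjacency) <- colnames(adjacency) <-
      sprintf("v%02d", seq_len(nrow(adjacency)))
  if (is.null(colnames(adjacency))) colnames(adjacency) <- rownames(adjacency)
  if (!identical(rownames(adjacency), colnames(adjacency)))
    stop("row and column names must agree")
  if (!is.null(kingdom)) {
    if (is.null(names(kingdom))) {
      if (length(kingdom) != nrow(adjacency))
        stop("kingdom labels must match node count")
      names(kingdom) <- rownames(adjacency)
    }
    kingdom <- kingdom[rownames(adjacency)]
    if (anyNA(kingdom)) stop("kingdom labels missing for some nodes")
  }
  structure(
    list(adjacency = adjacency, kingdom = kingdom,
         leaf_id = leaf_id, treatment = treatment, threshold = threshold),
    class = "directed_network"
  )
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d nodes, %d edges (leaf %s, %s, theta = %s)\n",
              n_nodes(x), n_edges(x), x$leaf_id, x$treatment,
              format(x$threshold)))
  invisible(x)
}

#' @rdname directed_network
#' @param net a `directed_network`.
#' @export
n_nodes <- function(net) nrow(net$adjacency)

#' @rdname directed_network
#' @export
n_edges <- function(net) sum(net$adjacency)

#' Edge list of a directed network
#' @param net a `directed_network`.
#' @return data.frame with columns `from`, `to` (isolate ids).
#' @export
edge_list <- function(net) {
  idx <- which(net$adjacency == 1L, arr.ind = TRUE)
  ids <- rownames(net$adjacency)
  df <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                   stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}

#' Convert to an igraph graph
#' @param net a `directed_network`.
#' @return an igraph object with a `kingdom` vertex attribute when labels are
#'   present.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed")
  if (!is.null(net$kingdom))
    g <- igraph::set_vertex_attr(g, "kingdom",
                                 value = unname(net$kingdom[rownames(net$adjacency)]))
  g
}

#' Threshold an overlap matrix into a binary competition network
#'
#' Draws an edge i -> j whenever the mean niche overlap of i on j reaches the
#' cutoff (`>=` theta); isolates with no edges are retained as isolated
#' nodes.
#'
#' @param matrix an [overlap_matrix()] (or plain numeric matrix).
#' @param theta overlap cutoff in `(0, 1]`; default 0.75.
#' @param kingdom optional kingdom labels when `matrix` is a plain matrix.
#' @return a [directed_network()].
#' @export
threshold_network <- function(matrix, theta = 0.75, kingdom = NULL) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1)
    stop("theta must lie in (0, 1]")
  vals <- unclass(matrix)
  adj <- (vals >= theta)
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  storage.mode(adj) <- "integer"
  directed_network(adj,
                   kingdom = kingdom %||% attr(matrix, "kingdom"),
                   leaf_id = attr(matrix, "leaf_id") %||% NA_character_,
                   treatment = attr(matrix, "treatment") %||% NA_character_,
                   threshold = theta)
}

#' Networks across a sweep of overlap cutoffs
#'
#' Edge sets are nested: raising theta can only remove edges.
#'
#' @param matrix an [overlap_matrix()].
#' @param theta_list numeric vector of cutoffs in `(0, 1]`.
#' @inheritParams threshold_network
#' @return named list of [directed_network()] objects, one per cutoff.
#' @export
threshold_sweep <- function(matrix, theta_list, kingdom = NULL) {
  out <- lapply(theta_list, function(th)
    threshold_network(matrix, th, kingdom = kingdom))
  names(out) <- format(theta_list)
  out
}
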