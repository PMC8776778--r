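#' Per-isolate degree records
#'
#' Indegree counts the isolates whose niche significantly overlaps the focal
#' isolate's; outdegree counts those the focal isolate overlaps. `prop_in`
#' is indegree / (indegree + outdegree), `NA` for nodes with no edges.
#' Degrees can be restricted to partners of the same or the other kingdom,
#' mirroring per-kingdom degree analyses.
#'
#' @param net a [directed_network()] with kingdom labels (labels are only
#'   required for kingdom-restricted filters).
#' @param partner_filter `"all"`, `"same_kingdom"` or `"cross_kingdom"`.
#' @return data.frame with columns `isolate_id`, `kingdom`, `indegree`,
#'   `outdegree`, `prop_in`, `partner_filter`.
#' @export
degree_records <- function(net, partner_filter = c("all", "same_kingdom",
                                                   "cross_kingdom")) {
  partner_filter <- match.arg(partner_filter)
  A <- net$adjacency
  ids <- rownames(A)
  kingdom <- net$kingdom
  if (partner_filter != "all" && is.null(kingdom))
    stop("kingdom labels required for kingdom-restricted degrees")
  if (partner_filter == "all") {
    mask <- matrix(TRUE, nrow(A), ncol(A))
  } else {
    same <- outer(kingdom[ids], kingdom[ids], "==")
    mask <- if (partner_filter == "same_kingdom") same else !same
  }
  Af <- A * mask
  indeg <- colSums(Af)
  outdeg <- rowSums(Af)
  tot <- indeg + outdeg
  data.frame(
    isolate_id = ids,
    kingdom = if (is.null(kingdom)) NA_character_ else unname(kingdom[ids]),
    indegree = unname(indeg),
    outdegree = unname(outdeg),
    prop_in = ifelse(tot > 0, indeg / tot, NA_real_),
    partner_filter = partner_filter,
    stringsAsFactors = FALSE
  )
}

#' Mean, standard deviation and skewness of a distribution
#'
#' Skewness is the moment coefficient g1 = m3 / m2^(3/2) with central moments
#' computed with 1/n normalization (no small-sample adjustment); it is `NA`
#' for constant samples. The standard deviation is the sample (n-1) sd.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return list with elements `mean`, `sd`, `skewness`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize")
  m <- mean(values)
  s <- stats::sd(values)
  if (is.na(s)) s <- 0
  dev <- values - m
  m2 <- mean(dev^2)
  skew <- if (m2 > 0) mean(dev^3) / m2^1.5 else NA_real_
  list(mean = m, sd = s, skewness = skew)
}

check_node <- function(net, node) {
  if (!node %in% rownames(net$adjacency))
    stop(sprintf("unknown node '%s'", node))
  node
}

#' Degree centrality of a node
#'
#' Total number of incoming plus outgoing links.
#'
#' @param net a [directed_network()].
#' @param node isolate id.
#' @return integer count.
#' @export
degree_centrality <- function(net, node) {
  check_node(net, node)
  unname(sum(net$adjacency[node, ]) + sum(net$adjacency[, node]))
}

#' Harmonic closeness centrality of a node
#'
#' Mean reciprocal shortest-path distance from (direction `"out"`) or to
#' (direction `"in"`) the focal node, normalized by n - 1; unreachable pairs
#' contribute 0, so the measure is well defined on disconnected networks.
#'
#' @param net a [directed_network()] with at least 2 nodes.
#' @param node isolate id.
#' @param direction `"out"` follows edge direction from the focal node,
#'   `"in"` follows edges toward it.
#' @return numeric in `[0, 1]`.
#' @export
closeness_centrality <- function(net, node, direction = c("out", "in")) {
  direction <- match.arg(direction)
  check_node(net, node)
  if (n_nodes(net) < 2L) stop("closeness requires at least 2 nodes")
  g <- as_igraph(net)
  unname(igraph::harmonic_centrality(g, vids = node, mode = direction,
                                     normalized = TRUE))
}

#' Local clustering coefficient of a node
#'
#' Watts-Strogatz local clustering computed on the underlying undirected
#' simple graph (edge directions collapsed, duplicates dropped): the
#' fraction of a node's neighbour pairs that are themselves connected.
#'
#' @param net a [directed_network()].
#' @param node isolate id.
#' @return numeric in `[0, 1]`, or `NA` for nodes with fewer than two
#'   neighbours.
#' @export
clustering_coefficient <- function(net, node) {
  check_node(net, node)
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  val <- igraph::transitivity(g, type = "local", vids = node,
                              isolates = "NaN")
  if (is.nan(val)) NA_real_ else unname(val)
}

#' Network intransitivity
#'
#' The fraction of directed 2-paths i -> j -> k (i != k) that are not closed
#' by a direct edge i -> k. Intransitive competitive loops (rock-paper-
#' scissors-like structure) have been proposed as a diversity-maintaining
#' mechanism; a fully transitive dominance hierarchy scores 0 and a union of
#' 3-cycles scores 1.
#'
#' @param net a [directed_network()].
#' @return numeric in `[0, 1]`, or `NA` when the network has no 2-paths.
#' @export
intransitivity <- function(net) {
  A <- net$adjacency
  A2 <- A %*% A
  total <- sum(A2) - sum(diag(A2))   # exclude i == k
  if (total == 0) return(NA_real_)
  closed <- sum(A2 * A)              # diag(A) is 0, so i == k never counts
  1 - closed / total
}

triad_classes <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                   "111U", "030T", "030C", "201", "120D", "120U", "120C",
                   "210", "300")

#' Directed triad census
#'
#' Counts, over all `choose(n, 3)` node triples, the 16 isomorphism classes
#' of directed graphs on three nodes, in the standard census order
#' (003, 012, 102, 021D, 021U, 021C, 111D, 111U, 030T, 030C, 201, 120D,
#' 120U, 120C, 210, 300), reported in the field as Triads 1-16.
#'
#' @param net a [directed_network()] with at least 3 nodes.
#' @return named integer vector of length 16 summing to `choose(n, 3)`.
#' @export
triad_census <- function(net) {
  if (n_nodes(net) < 3L) stop("triad census requires at least 3 nodes")
  counts <- igraph::triad_census(as_igraph(net))
  stats::setNames(as.integer(counts), triad_classes)
}

#' Whole-network structural summary
#'
#' Assembles node and edge counts, connectance (realized fraction of the
#' `n(n-1)` possible directed links), mean local clustering over nodes where
#' it is defined, intransitivity, and mean/sd/skewness summaries of the in-,
#' out-, and proportion-inbound degree distributions.
#'
#' @param net a [directed_network()].
#' @return one-row data.frame.
#' @export
network_summary <- function(net) {
  n <- n_nodes(net)
  e <- n_edges(net)
  recs <- degree_records(net)
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  cl <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cl <- cl[!is.nan(cl)]
  din <- summarize_distribution(recs$indegree)
  dout <- summarize_distribution(recs$outdegree)
  dprop <- if (all(is.na(recs$prop_in))) list(mean = NA_real_, sd = NA_real_,
                                              skewness = NA_real_)
           else summarize_distribution(recs$prop_in)
  data.frame(
    leaf_id = net$leaf_id, treatment = net$treatment,
    n_nodes = n, n_edges = e,
    connectance = if (n > 1L) e / (n * (n - 1L)) else NA_real_,
    mean_clustering = if (length(cl)) mean(cl) else NA_real_,
    intransitivity = intransitivity(net),
    indegree_mean = din$mean, indegree_sd = din$sd,
    indegree_skewness = din$skewness,
    outdegree_mean = dout$mean, outdegree_sd = dout$sd,
    outdegree_skewness = dout$skewness,
    prop_in_mean = dprop$mean, prop_in_sd = dprop$sd,
    prop_in_skewness = dprop$skewness,
    stringsAsFactors = FALSE
  )
}
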