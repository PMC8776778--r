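# Brute-force reference implementations, independent of the package's
# (igraph-backed) metric code. Used to validate triad census, closeness,
# clustering and intransitivity exactly on small random graphs.

# --- triad classification by permutation closure -------------------------
# Representatives of the 16 directed triad classes on nodes {1,2,3}, edges
# given as from->to pairs, in standard census order.
triad_reps <- list(
  "003"  = cbind(integer(0), integer(0)),
  "012"  = rbind(c(1, 2)),
  "102"  = rbind(c(1, 2), c(2, 1)),
  "021D" = rbind(c(2, 1), c(2, 3)),
  "021U" = rbind(c(1, 2), c(3, 2)),
  "021C" = rbind(c(1, 2), c(2, 3)),
  "111D" = rbind(c(1, 2), c(2, 1), c(3, 2)),
  "111U" = rbind(c(1, 2), c(2, 1), c(2, 3)),
  "030T" = rbind(c(1, 2), c(3, 2), c(1, 3)),
  "030C" = rbind(c(2, 1), c(3, 2), c(1, 3)),
  "201"  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),
  "120D" = rbind(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),
  "120U" = rbind(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),
  "120C" = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),
  "210"  = rbind(c(1, 2), c(2, 3), c(3, 2), c(1, 3), c(3, 1)),
  "300"  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1))
)

triad_code <- function(A) {
  # 6-bit code over ordered pairs (1,2),(1,3),(2,1),(2,3),(3,1),(3,2)
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  sum(A[pairs] * 2^(0:5))
}

# dictionary: 64 labeled 3-node digraphs -> class name
triad_dictionary <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  dict <- rep(NA_character_, 64)
  for (cls in names(triad_reps)) {
    A <- matrix(0L, 3, 3)
    ep <- triad_reps[[cls]]
    if (nrow(ep)) A[ep] <- 1L
    for (p in perms) {
      code <- triad_code(A[p, p])
      if (!is.na(dict[code + 1]) && dict[code + 1] != cls)
        stop("triad representatives are not isomorphism-distinct")
      dict[code + 1] <- cls
    }
  }
  if (anyNA(dict)) stop("triad dictionary does not cover all 64 digraphs")
  dict
})

oracle_triad_census <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  counts <- stats::setNames(integer(16), names(triad_reps))
  triples <- utils::combn(n, 3)
  for (k in seq_len(ncol(triples))) {
    sub <- A[triples[, k], triples[, k]]
    cls <- triad_dictionary[triad_code(sub) + 1]
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

# --- all-pairs BFS harmonic closeness ------------------------------------
oracle_bfs_dist <- function(A, src) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) nxt <- c(nxt, which(A[v, ] == 1L))
    nxt <- unique(nxt[is.infinite(dist[nxt])])
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

oracle_closeness <- function(net, node, direction) {
  A <- net$adjacency
  if (direction == "in") A <- t(A)
  i <- match(node, rownames(net$adjacency))
  d <- oracle_bfs_dist(A, i)[-i]
  sum(1 / d[d > 0], na.rm = TRUE) / (nrow(A) - 1)
}

# --- triangle-enumeration clustering -------------------------------------
oracle_clustering <- function(net, node) {
  U <- (net$adjacency + t(net$adjacency)) > 0
  i <- match(node, rownames(net$adjacency))
  nb <- which(U[i, ])
  k <- length(nb)
  if (k < 2) return(NA_real_)
  pairs <- utils::combn(nb, 2)
  tri <- sum(U[t(pairs)])
  tri / choose(k, 2)
}

# --- 2-path enumeration intransitivity -----------------------------------
oracle_intransitivity <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  total <- 0L
  closed <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k && A[i, j] == 1L && A[j, k] == 1L) {
      total <- total + 1L
      if (A[i, k] == 1L) closed <- closed + 1L
    }
  }
  if (total == 0L) return(NA_real_)
  1 - closed / total
}

# --- random graph fixtures ------------------------------------------------
random_net <- function(n, p, kingdom = NULL) {
  A <- matrix(rbinom(n * n, 1L, p), n, n)
  diag(A) <- 0L
  dimnames(A) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  directed_network(A, kingdom = kingdom)
}

# small hand-built network from an edge list on named nodes
net_from_edges <- function(nodes, edges, kingdom = NULL) {
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (length(edges)) for (e in edges) A[e[1], e[2]] <- 1L
  directed_network(A, kingdom = kingdom)
}
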