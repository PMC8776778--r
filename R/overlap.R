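#' Per-substrate niche overlap
#'
#' For a single substrate, the overlap of isolate i on isolate j is the
#' capped growth ratio `min(g_i / g_j, 1)`: the fraction of j's growth on
#' that substrate matched by i. It is defined only where both isolates show
#' non-zero growth; elsewhere the value is `NA` (and contributes 0 to the
#' substrate average, see [mean_overlap()]).
#'
#' @param g_i,g_j non-negative growth values (optical densities); vectors are
#'   handled elementwise.
#' @return numeric in `[0, 1]`, `NA` where either input is zero.
#' @export
substrate_overlap <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) stop("growth vectors differ in length")
  if (any(g_i < 0) || any(g_j < 0)) stop("growth values must be non-negative")
  out <- rep(NA_real_, length(g_i))
  both <- g_i > 0 & g_j > 0
  out[both] <- pmin(g_i[both] / g_j[both], 1)
  out
}

#' Mean directed niche overlap between two profiles
#'
#' Averages the per-substrate capped ratios over all substrates, with
#' substrates where either isolate shows zero growth contributing 0; the
#' denominator is always the full substrate count, treating every substrate
#' as equally important in defining the resource niche.
#'
#' @param g_i,g_j growth vectors of equal length (the two isolates' profiles
#'   over the same substrate panel).
#' @return the mean overlap of i on j, in `[0, 1]`.
#' @export
mean_overlap <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) stop("growth vectors differ in length")
  omega <- substrate_overlap(g_i, g_j)
  sum(omega, na.rm = TRUE) / length(omega)
}

#' Directed niche-overlap matrix of a community
#'
#' Fills all `m(m-1)` ordered pairs; the diagonal is `NA` (self-overlap is
#' not applicable). The matrix is generally asymmetric: i overlapping j
#' substantially does not imply the reverse.
#'
#' @param community a [community_table()].
#' @return an `overlap_matrix`: an m x m numeric matrix with isolate ids as
#'   dimnames and attributes `kingdom`, `leaf_id`, `treatment`.
#' @export
overlap_matrix <- function(community) {
  if (!inherits(community, "community_table"))
    stop("expected a community_table")
  g <- community$growth
  m <- nrow(g)
  if (m < 2L) stop("need at least 2 isolates")
  ns <- ncol(g)
  pos <- g > 0
  om <- matrix(NA_real_, m, m, dimnames = list(rownames(g), rownames(g)))
  for (j in seq_len(m)) {
    # capped ratios of every isolate against j, zeroed where either is absent
    ratio <- pmin(sweep(g, 2L, g[j, ], "/"), 1)
    ratio[!pos] <- 0
    ratio[, !pos[j, ]] <- 0
    om[, j] <- rowSums(ratio) / ns
  }
  diag(om) <- NA_real_
  structure(om,
            kingdom = stats::setNames(community$isolates$kingdom,
                                      community$isolates$isolate_id),
            leaf_id = community$leaf_id,
            treatment = community$treatment,
            class = c("overlap_matrix", "matrix", "array"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("overlap_matrix: %d isolates, leaf %s (%s)\n",
              nrow(x), attr(x, "leaf_id") %||% "?",
              attr(x, "treatment") %||% "?"))
  print(unclass(x)[, , drop = FALSE], digits = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
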