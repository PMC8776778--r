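#' Degree-preserving rewiring of a directed network
#'
#' Runs a Markov chain of directed double-edge swaps: two edges a -> b and
#' c -> d (all four endpoints pairwise compatible, neither a -> d nor c -> b
#' already present) are replaced by a -> d and c -> b. Every node's in- and
#' outdegree, the edge count, and graph simplicity (no self-loops, no
#' duplicate edges) are preserved exactly; only who connects to whom is
#' randomized. This is the configuration-model null used to ask whether
#' observed structure exceeds what the pairwise interaction counts dictate.
#'
#' @param net a [directed_network()].
#' @param n_swaps number of successful swaps to perform (default
#'   `10 * n_edges(net)`, a standard mixing heuristic).
#' @param seed integer seed (deterministic output) or `NULL` to use the
#'   current RNG stream.
#' @param max_tries cap on attempted swaps, so networks with no legal swap
#'   (e.g. a single edge, or a complete graph) terminate unchanged.
#' @return a [directed_network()] with identical degree sequences.
#' @export
rewire_preserving_degrees <- function(net, n_swaps = 10 * n_edges(net),
                                      seed = NULL,
                                      max_tries = 100 * n_swaps + 1000) {
  if (n_swaps < 0) stop("n_swaps must be >= 0")
  el <- which(net$adjacency == 1L, arr.ind = TRUE)
  if (nrow(el) < 2L || n_swaps == 0) return(net)
  new_el <- with_seed(seed,
    rewire_edges_cpp(el, n_nodes(net), as.integer(n_swaps),
                     as.double(max_tries)))
  A <- matrix(0L, n_nodes(net), n_nodes(net),
              dimnames = dimnames(net$adjacency))
  A[new_el] <- 1L
  out <- net
  out$adjacency <- A
  out
}

# canonical serialization of the labelled edge set, for uniqueness counting
serialize_edges <- function(net) {
  el <- which(net$adjacency == 1L)
  paste(el, collapse = ",")
}

#' Null ensemble of a network metric under the configuration model
#'
#' Draws `n_rand` degree-preserving randomizations (each a fresh swap chain
#' from the observed network) and evaluates a metric on each. The number of
#' unique labelled configurations visited is recorded: highly nested
#' networks can have so few admissible configurations that randomization
#' tests are uninformative.
#'
#' @param net a [directed_network()].
#' @param metric_fn function mapping a `directed_network` to a single number.
#' @param n_rand ensemble size (default 1000).
#' @param swaps_per_sample successful swaps per sample; default
#'   `10 * n_edges(net)`.
#' @param seed integer seed for the whole ensemble.
#' @return object of class `null_ensemble`: list with `metric_name`,
#'   `observed`, `null_values`, `n_unique_configurations`, `seed`.
#' @export
null_ensemble <- function(net, metric_fn, n_rand = 1000,
                          swaps_per_sample = NULL, seed = NULL) {
  if (n_rand < 1) stop("n_rand must be >= 1")
  if (is.null(swaps_per_sample)) swaps_per_sample <- 10 * n_edges(net)
  metric_name <- deparse(substitute(metric_fn))[1]
  observed <- metric_fn(net)
  res <- with_seed(seed, {
    vals <- numeric(n_rand)
    keys <- character(n_rand)
    for (r in seq_len(n_rand)) {
      nr <- rewire_preserving_degrees(net, n_swaps = swaps_per_sample,
                                      seed = NULL)
      vals[r] <- metric_fn(nr)
      keys[r] <- serialize_edges(nr)
    }
    list(vals = vals, keys = keys)
  })
  structure(
    list(metric_name = metric_name, observed = observed,
         null_values = res$vals,
         n_unique_configurations = length(unique(res$keys)),
         seed = seed),
    class = "null_ensemble"
  )
}

#' Empirical p-value against a null distribution
#'
#' Mid-p rank of the observed value in the null sample:
#' `p = (#\{null < obs\} + 0.5 #\{null = obs\}) / N`. Values below 0.05 flag
#' the observation as smaller than expected under the null, values above
#' 0.95 as larger. Ties are split because configuration-model null supports
#' can be tiny, making exact ties common.
#'
#' @param observed observed metric value.
#' @param null_values numeric vector of null draws.
#' @return numeric in `[0, 1]`.
#' @export
empirical_p <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) == 0L) stop("empty null distribution")
  if (is.na(observed)) return(NA_real_)
  (sum(null_values < observed) + 0.5 * sum(null_values == observed)) /
    length(null_values)
}

#' z-score against a null distribution
#'
#' `(observed - mean(null)) / sd(null)`, a magnitude measure to accompany
#' [empirical_p()]; `|z| > 2` marks substantial deviation. `NA` when the
#' null is constant.
#'
#' @inheritParams empirical_p
#' @return numeric, or `NA` when the null sd is 0.
#' @export
z_score <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) == 0L) stop("empty null distribution")
  if (length(null_values) < 2L) stop("z score requires >= 2 null values")
  s <- stats::sd(null_values)
  if (is.na(observed) || s == 0) return(NA_real_)
  (observed - mean(null_values)) / s
}

# default HOI metric suite: mean clustering, intransitivity, 16 triad counts
hoi_metric_values <- function(net) {
  s <- network_summary(net)
  c(mean_clustering = s$mean_clustering,
    intransitivity = s$intransitivity,
    stats::setNames(as.numeric(triad_census(net)),
                    paste0("triad_", triad_classes)))
}

#' Randomization test for higher-order interactions
#'
#' Compares observed structural metrics of a network to their distributions
#' over a shared configuration-model ensemble (degree sequences fixed,
#' connections randomized). Structure that pairwise interaction counts alone
#' cannot explain — candidate higher-order interactions — shows up as
#' empirical p below 0.05 (smaller than expected) or above 0.95 (larger),
#' with z scores giving magnitude. Networks whose ensembles visit fewer than
#' `min_unique` distinct configurations are flagged degenerate: their
#' structure is essentially dictated by their degree distribution and the
#' test is uninformative.
#'
#' @param net a [directed_network()] with at least 3 nodes.
#' @param metric_suite named list of functions `directed_network -> number`;
#'   default: mean local clustering, intransitivity, and the 16 triad
#'   counts.
#' @param n_rand ensemble size (default 1000).
#' @param swaps_per_sample successful swaps per ensemble member; default
#'   `10 * n_edges(net)`.
#' @param seed integer seed.
#' @param min_unique minimum distinct configurations for a non-degenerate
#'   test (default 5).
#' @return data.frame (class `hoi_result`) with one row per metric:
#'   `metric`, `observed`, `null_mean`, `null_sd`, `empirical_p`, `z`,
#'   `n_unique_configurations`, `flag` in
#'   `{lower, higher, ns, degenerate}`.
#' @export
hoi_test <- function(net, metric_suite = NULL, n_rand = 1000,
                     swaps_per_sample = NULL, seed = NULL, min_unique = 5) {
  if (is.null(swaps_per_sample)) swaps_per_sample <- 10 * n_edges(net)
  if (is.null(metric_suite)) {
    eval_fn <- hoi_metric_values
  } else {
    if (length(metric_suite) == 0L) stop("metric_suite must be non-empty")
    if (is.null(names(metric_suite)) || any(names(metric_suite) == ""))
      stop("metric_suite must be a named list")
    eval_fn <- function(x) vapply(metric_suite, function(f) f(x), numeric(1))
  }
  observed <- eval_fn(net)
  res <- with_seed(seed, {
    vals <- matrix(NA_real_, n_rand, length(observed),
                   dimnames = list(NULL, names(observed)))
    keys <- character(n_rand)
    for (r in seq_len(n_rand)) {
      nr <- rewire_preserving_degrees(net, n_swaps = swaps_per_sample,
                                      seed = NULL)
      vals[r, ] <- eval_fn(nr)
      keys[r] <- serialize_edges(nr)
    }
    list(vals = vals, n_unique = length(unique(keys)))
  })
  degenerate <- res$n_unique < min_unique
  out <- do.call(rbind, lapply(seq_along(observed), function(k) {
    nv <- res$vals[, k]
    p <- empirical_p(observed[k], nv)
    z <- if (sum(!is.na(nv)) >= 2L) z_score(observed[k], nv) else NA_real_
    flag <- if (degenerate) "degenerate"
            else if (is.na(p)) "ns"
            else if (p < 0.05) "lower"
            else if (p > 0.95) "higher"
            else "ns"
    data.frame(metric = names(observed)[k], observed = unname(observed[k]),
               null_mean = mean(nv, na.rm = TRUE),
               null_sd = stats::sd(nv[!is.na(nv)]),
               empirical_p = p, z = z,
               n_unique_configurations = res$n_unique,
               flag = flag, stringsAsFactors = FALSE)
  }))
  attr(out, "leaf_id") <- net$leaf_id
  attr(out, "treatment") <- net$treatment
  class(out) <- c("hoi_result", "data.frame")
  out
}

#' Table of HOI results across communities
#'
#' Binds per-network [hoi_test()] results into a metrics-by-communities
#' table of empirical p and z, with a significance glyph per cell:
#' `"<"`/`"<<"` for p < 0.05 / 0.01 (smaller than expected), `">"`/`">>"`
#' for p > 0.95 / 0.99, `"-"` for non-significant, `"x"` for degenerate
#' cells.
#'
#' @param results named list of [hoi_test()] outputs (names = leaf ids).
#' @return data.frame in long form: `leaf_id`, `metric`, `empirical_p`,
#'   `z`, `glyph`.
#' @export
hoi_table <- function(results) {
  do.call(rbind, lapply(names(results), function(leaf) {
    r <- results[[leaf]]
    glyph <- ifelse(r$flag == "degenerate", "x",
             ifelse(is.na(r$empirical_p), "x",
             ifelse(r$empirical_p < 0.01, "<<",
             ifelse(r$empirical_p < 0.05, "<",
             ifelse(r$empirical_p > 0.99, ">>",
             ifelse(r$empirical_p > 0.95, ">", "-"))))))
    data.frame(leaf_id = leaf, metric = r$metric,
               empirical_p = r$empirical_p, z = r$z, glyph = glyph,
               stringsAsFactors = FALSE)
  }))
}
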