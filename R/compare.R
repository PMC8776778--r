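#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom. Groups in
#' which both samples are constant are handled explicitly: equal means give
#' t = 0, p = 1 (identical groups are never "different"), unequal constant
#' means give infinite t and p = 0.
#'
#' @param values_a,values_b numeric vectors, each with at least 2 values.
#' @param metric_name,group_labels optional labels carried into the result.
#' @return one-row data.frame: `metric`, `group_a`, `group_b`, `mean_a`,
#'   `mean_b`, `t_stat`, `df`, `p_raw`.
#' @export
welch_t <- function(values_a, values_b, metric_name = NA_character_,
                    group_labels = c("a", "b")) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  va <- stats::var(values_a)
  vb <- stats::var(values_b)
  ma <- mean(values_a)
  mb <- mean(values_b)
  if (va + vb == 0) {
    t_stat <- if (ma == mb) 0 else sign(ma - mb) * Inf
    df <- NA_real_
    p <- if (ma == mb) 1 else 0
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  data.frame(metric = metric_name, group_a = group_labels[1],
             group_b = group_labels[2], mean_a = ma, mean_b = mb,
             t_stat = t_stat, df = df, p_raw = p, stringsAsFactors = FALSE)
}

#' Multiple-testing correction of p-values
#'
#' Benjamini-Hochberg step-up adjustment by default; the method is carried
#' as an attribute so results record how they were corrected. `NA`s pass
#' through.
#'
#' @param p_list numeric vector of p-values in `[0, 1]`.
#' @param method a `p.adjust` method name (default `"BH"`).
#' @return adjusted p-values in `[0, 1]`, attribute `method`.
#' @export
adjust_pvalues <- function(p_list, method = "BH") {
  ok <- !is.na(p_list)
  if (any(p_list[ok] < 0 | p_list[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- stats::p.adjust(p_list, method = method)
  attr(out, "method") <- method
  out
}

#' Linear fit of indegree on outdegree
#'
#' Ordinary least squares of indegree (response) on outdegree (predictor)
#' over a subset of degree records, optionally restricted by focal kingdom,
#' partner filter, and treatment. A negative slope is the signature of a
#' dominance hierarchy: isolates that overlap many others are themselves
#' overlapped by few.
#'
#' @param records data.frame from [degree_records()], optionally with a
#'   `treatment` column.
#' @param focal_kingdom optional `"bacteria"`/`"fungi"` filter.
#' @param partner_filter optional filter on the `partner_filter` column.
#' @param treatment optional `"control"`/`"NPK"` filter.
#' @return one-row data.frame: `focal_kingdom`, `partner_filter`,
#'   `treatment`, `slope`, `intercept`, `slope_p`, `n_points`, `degenerate`
#'   (`TRUE` when all outdegrees are equal, leaving the slope undefined).
#' @export
fit_degree_slope <- function(records, focal_kingdom = NULL,
                             partner_filter = NULL, treatment = NULL) {
  sub <- records
  if (!is.null(focal_kingdom)) sub <- sub[sub$kingdom %in% focal_kingdom, ]
  if (!is.null(partner_filter))
    sub <- sub[sub$partner_filter %in% partner_filter, ]
  if (!is.null(treatment) && "treatment" %in% names(sub))
    sub <- sub[sub$treatment %in% treatment, ]
  if (nrow(sub) < 3L) stop("need at least 3 records for a slope fit")
  base <- data.frame(
    focal_kingdom = if (is.null(focal_kingdom)) "all" else focal_kingdom,
    partner_filter = if (is.null(partner_filter)) "all" else partner_filter,
    treatment = if (is.null(treatment)) "all" else treatment,
    n_points = nrow(sub), stringsAsFactors = FALSE)
  if (length(unique(sub$outdegree)) == 1L) {
    return(cbind(base, slope = NA_real_, intercept = NA_real_,
                 slope_p = NA_real_, degenerate = TRUE))
  }
  fit <- stats::lm(indegree ~ outdegree, data = sub)
  co <- summary(fit)$coefficients
  cbind(base,
        slope = unname(co["outdegree", "Estimate"]),
        intercept = unname(co["(Intercept)", "Estimate"]),
        slope_p = unname(co["outdegree", "Pr(>|t|)"]),
        degenerate = FALSE)
}

#' Modularity-based community detection
#'
#' Partitions a network (or a weighted overlap matrix) into modules with the
#' spin-glass (Potts model) algorithm, run per connected component of the
#' undirected collapse; isolated nodes become singleton modules. The
#' stochastic optimizer is seeded for reproducibility.
#'
#' @param x a [directed_network()], or an [overlap_matrix()] when
#'   `weighted = TRUE`.
#' @param weighted if `TRUE`, `x` must be an overlap matrix; edges carry the
#'   mean overlap as weight.
#' @param seed integer seed.
#' @return list of class `community_assignment`: `membership` (named integer
#'   vector), `modularity`, `method`, `seed`.
#' @export
detect_communities <- function(x, weighted = FALSE, seed = NULL) {
  if (weighted) {
    if (!inherits(x, "overlap_matrix"))
      stop("weighted detection needs an overlap_matrix")
    W <- unclass(x)
    W[is.na(W)] <- 0
    g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                             weighted = TRUE)
  } else {
    if (!inherits(x, "directed_network"))
      stop("expected a directed_network (or weighted = TRUE with a matrix)")
    g <- as_igraph(x)
  }
  if (igraph::vcount(g) == 0L) stop("empty network")
  und <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "mean", "ignore"))
  comp <- igraph::components(und)
  membership <- integer(igraph::vcount(und))
  names(membership) <- igraph::V(und)$name
  next_label <- 0L
  with_seed(seed, {
    for (cid in seq_len(comp$no)) {
      vs <- which(comp$membership == cid)
      if (length(vs) == 1L || sum(igraph::degree(und, vs)) == 0) {
        membership[vs] <- next_label + 1L
        next_label <- next_label + 1L
      } else {
        sub <- igraph::induced_subgraph(und, vs)
        cl <- igraph::cluster_spinglass(sub, spins = min(25L, length(vs)))
        membership[vs] <- next_label + igraph::membership(cl)
        next_label <- next_label + max(igraph::membership(cl))
      }
    }
  })
  mod <- igraph::modularity(und, membership,
                            weights = igraph::E(und)$weight)
  structure(list(membership = membership, modularity = mod,
                 method = "spinglass", seed = seed),
            class = "community_assignment")
}

#' Association between module membership and kingdom
#'
#' Pearson chi-squared test (no continuity correction) of the modules x
#' kingdom contingency table. When any expected count falls below 5 the
#' p-value is computed by Monte-Carlo permutation (10,000 draws, seeded)
#' instead of the asymptotic distribution. Returns a not-applicable result
#' when fewer than two modules or kingdoms are present.
#'
#' @param assignment a [detect_communities()] result (or named membership
#'   vector).
#' @param kingdoms named character vector of kingdom labels.
#' @param n_permutations Monte-Carlo draws for small tables.
#' @param seed integer seed for the Monte-Carlo path.
#' @return list: `chi2`, `df`, `p`, `method`, `table`.
#' @export
kingdom_association <- function(assignment, kingdoms,
                                n_permutations = 10000, seed = NULL) {
  membership <- if (inherits(assignment, "community_assignment"))
    assignment$membership else assignment
  kingdoms <- kingdoms[names(membership)]
  tab <- table(module = membership, kingdom = kingdoms)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(chi2 = NA_real_, df = NA_real_, p = NA_real_,
                method = "not-applicable", table = tab))
  }
  asym <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(asym$expected < 5)) {
    mc <- with_seed(seed,
      suppressWarnings(stats::chisq.test(tab, correct = FALSE,
                                         simulate.p.value = TRUE,
                                         B = n_permutations)))
    list(chi2 = unname(asym$statistic), df = unname(asym$parameter),
         p = mc$p.value, method = "monte-carlo", table = tab)
  } else {
    list(chi2 = unname(asym$statistic), df = unname(asym$parameter),
         p = asym$p.value, method = "asymptotic", table = tab)
  }
}

# Welch test tolerant of degenerate groups; returns NA row when both groups
# are all-NA or too small (e.g. a metric undefined on every network).
welch_row <- function(a, b, metric, labels) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(data.frame(metric = metric, group_a = labels[1],
                      group_b = labels[2], mean_a = mean(a), mean_b = mean(b),
                      t_stat = NA_real_, df = NA_real_, p_raw = NA_real_,
                      stringsAsFactors = FALSE))
  }
  welch_t(a, b, metric_name = metric, group_labels = labels)
}

#' Cross-group comparisons over a study's networks
#'
#' With `grouping = "treatment"`, compares control vs NPK networks on (i)
#' whole-network metrics (connectance, clustering, intransitivity, degree
#' distribution summaries) and (ii) the 16 triad counts, with
#' multiple-testing correction applied separately within each family. Triad
#' classes absent from every network in both groups yield `NA` rows. With
#' `grouping = "kingdom"`, runs per-network bacteria-vs-fungi Welch tests of
#' node clustering, degree centrality and directional closeness, corrected
#' across the whole family.
#'
#' @param networks list of [directed_network()] objects.
#' @param grouping `"treatment"` or `"kingdom"`.
#' @param exclude_undersized drop networks with fewer than `min_nodes`
#'   isolates from treatment comparisons (the study design's outlying small
#'   community).
#' @param min_nodes node-count threshold used by `exclude_undersized`.
#' @param correction `p.adjust` method (default `"BH"`).
#' @return data.frame of Welch results with columns `family`, `metric`,
#'   (for kingdom grouping) `leaf_id`, `t_stat`, `df`, `p_raw`,
#'   `p_adjusted`.
#' @export
study_comparison <- function(networks, grouping = c("treatment", "kingdom"),
                             exclude_undersized = TRUE, min_nodes = 20,
                             correction = "BH") {
  grouping <- match.arg(grouping)
  if (grouping == "treatment") {
    if (exclude_undersized)
      networks <- Filter(function(nt) n_nodes(nt) >= min_nodes, networks)
    trt <- vapply(networks, function(nt) nt$treatment, character(1))
    if (length(unique(trt)) < 2L) stop("need networks from both treatments")
    summaries <- do.call(rbind, lapply(networks, network_summary))
    global_metrics <- c("connectance", "mean_clustering", "intransitivity",
                        "indegree_mean", "indegree_sd", "indegree_skewness",
                        "outdegree_mean", "outdegree_sd",
                        "outdegree_skewness", "prop_in_mean", "prop_in_sd",
                        "prop_in_skewness")
    glob <- do.call(rbind, lapply(global_metrics, function(mname) {
      welch_row(summaries[[mname]][trt == "control"],
                summaries[[mname]][trt == "NPK"],
                mname, c("control", "NPK"))
    }))
    glob$family <- "global_metrics"
    census <- t(vapply(networks, triad_census, integer(16)))
    tri <- do.call(rbind, lapply(seq_len(16), function(k) {
      a <- census[trt == "control", k]
      b <- census[trt == "NPK", k]
      mname <- paste0("triad_", triad_classes[k])
      if (all(a == 0) && all(b == 0)) {
        data.frame(metric = mname, group_a = "control", group_b = "NPK",
                   mean_a = NA_real_, mean_b = NA_real_, t_stat = NA_real_,
                   df = NA_real_, p_raw = NA_real_, stringsAsFactors = FALSE)
      } else {
        welch_row(a, b, mname, c("control", "NPK"))
      }
    }))
    tri$family <- "triad_counts"
    out <- rbind(glob, tri)
    out$leaf_id <- NA_character_
  } else {
    out <- do.call(rbind, lapply(networks, function(nt) {
      if (is.null(nt$kingdom)) stop("kingdom grouping needs kingdom labels")
      ids <- rownames(nt$adjacency)
      king <- nt$kingdom[ids]
      vals <- list(
        clustering = vapply(ids, function(v) {
          cc <- clustering_coefficient(nt, v)
          if (is.na(cc)) NA_real_ else cc
        }, numeric(1)),
        degree_centrality = vapply(ids, function(v)
          as.numeric(degree_centrality(nt, v)), numeric(1)),
        closeness_in = vapply(ids, function(v)
          closeness_centrality(nt, v, "in"), numeric(1)),
        closeness_out = vapply(ids, function(v)
          closeness_centrality(nt, v, "out"), numeric(1))
      )
      rows <- do.call(rbind, lapply(names(vals), function(mname) {
        welch_row(vals[[mname]][king == "bacteria"],
                  vals[[mname]][king == "fungi"],
                  mname, c("bacteria", "fungi"))
      }))
      rows$leaf_id <- nt$leaf_id
      rows
    }))
    out$family <- "kingdom_node_metrics"
  }
  out$p_adjusted <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_adjusted[sel] <- adjust_pvalues(out$p_raw[sel], method = correction)
  }
  attr(out, "correction") <- correction
  rownames(out) <- NULL
  out
}
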