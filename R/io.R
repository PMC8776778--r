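#' Write a study's growth data to a delimited table
#'
#' Two dialects: `"long"` has one row per isolate x substrate
#' (`isolate_id`, `kingdom`, `leaf_id`, `treatment`, `substrate_index`,
#' `growth`); `"wide"` has one row per isolate with substrate columns
#' `g1..gN`. Both round-trip through [read_growth_table()].
#'
#' @param study list of [community_table()] objects (a single community is
#'   accepted).
#' @param path output file (CSV).
#' @param dialect `"long"` or `"wide"`.
#' @export
write_growth_table <- function(study, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (inherits(study, "community_table")) study <- list(study)
  rows <- lapply(study, function(cm) {
    g <- cm$growth
    meta <- data.frame(isolate_id = rownames(g),
                       kingdom = cm$isolates$kingdom,
                       leaf_id = cm$leaf_id, treatment = cm$treatment,
                       stringsAsFactors = FALSE)
    if (dialect == "long") {
      data.frame(meta[rep(seq_len(nrow(g)), each = ncol(g)), ],
                 substrate_index = rep(seq_len(ncol(g)), nrow(g)),
                 growth = as.vector(t(g)), row.names = NULL,
                 stringsAsFactors = FALSE)
    } else {
      wide <- as.data.frame(g)
      names(wide) <- paste0("g", seq_len(ncol(g)))
      cbind(meta, wide, row.names = NULL)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a growth table into communities
#'
#' Validates as it reads: missing or negative growth values are rejected
#' with row-level diagnostics, and every isolate of a community must share
#' its leaf's treatment.
#'
#' @param path CSV written by [write_growth_table()] (either dialect).
#' @param dialect `"long"` or `"wide"`.
#' @return named list of [community_table()] objects, one per leaf.
#' @export
read_growth_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("isolate_id", "kingdom", "leaf_id", "treatment",
            if (dialect == "long") c("substrate_index", "growth"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  gcols <- if (dialect == "long") "growth" else grep("^g\\d+$", names(df),
                                                     value = TRUE)
  if (dialect == "wide" && length(gcols) == 0L)
    stop("wide dialect needs substrate columns g1..gN")
  gdf <- df[, gcols, drop = FALSE]
  bad <- which(rowSums(is.na(gdf)) > 0 | rowSums(gdf < 0, na.rm = TRUE) > 0)
  if (length(bad))
    stop("invalid growth values (missing or negative) at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  leaves <- unique(df$leaf_id)
  out <- lapply(leaves, function(leaf) {
    sub <- df[df$leaf_id == leaf, , drop = FALSE]
    trt <- unique(sub$treatment)
    if (length(trt) != 1L)
      stop(sprintf("leaf %s has conflicting treatments", leaf))
    if (dialect == "long") {
      ids <- unique(sub$isolate_id)
      ns <- max(sub$substrate_index)
      g <- matrix(NA_real_, length(ids), ns,
                  dimnames = list(ids, NULL))
      g[cbind(match(sub$isolate_id, ids), sub$substrate_index)] <- sub$growth
      if (anyNA(g)) stop(sprintf("leaf %s: incomplete substrate grid", leaf))
      kingdom <- sub$kingdom[match(ids, sub$isolate_id)]
    } else {
      g <- as.matrix(sub[gcols])
      rownames(g) <- sub$isolate_id
      kingdom <- sub$kingdom
    }
    community_table(g, kingdom, leaf, trt)
  })
  names(out) <- leaves
  out
}

#' Write an overlap matrix as square CSV
#' @param om an [overlap_matrix()].
#' @param path output CSV (isolate ids as header row and first column).
#' @export
write_overlap_matrix <- function(om, path) {
  utils::write.csv(as.data.frame(unclass(om)), path, row.names = TRUE)
  invisible(path)
}

#' Write an overlap matrix as a long edge table
#' @param om an [overlap_matrix()].
#' @param path output CSV with columns `source`, `target`, `weight`.
#' @export
write_overlap_edges <- function(om, path) {
  ids <- rownames(om)
  idx <- which(!is.na(unclass(om)), arr.ind = TRUE)
  df <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                   weight = unclass(om)[idx], stringsAsFactors = FALSE)
  utils::write.csv(df[order(df$source, df$target), ], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write / read a network edge list (TSV)
#'
#' The node universe (including isolated nodes) and kingdom labels travel in
#' commented header lines so the network round-trips exactly.
#'
#' @param net a [directed_network()].
#' @param path TSV path.
#' @export
write_edge_list <- function(net, path) {
  ids <- rownames(net$adjacency)
  hdr <- c(paste0("# nodes: ", paste(ids, collapse = ",")),
           if (!is.null(net$kingdom))
             paste0("# kingdom: ", paste(net$kingdom[ids], collapse = ",")),
           paste0("# leaf_id: ", net$leaf_id),
           paste0("# treatment: ", net$treatment),
           paste0("# threshold: ", format(net$threshold)))
  el <- edge_list(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("from\tto", con)
  if (nrow(el))
    writeLines(paste(el$from, el$to, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @return `read_edge_list()` returns a [directed_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getfield <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NA_character_
  }
  ids <- strsplit(getfield("nodes"), ",")[[1]]
  kingdom <- getfield("kingdom")
  kingdom <- if (is.na(kingdom)) NULL
             else stats::setNames(strsplit(kingdom, ",")[[1]], ids)
  body <- lines[!grepl("^#", lines)]
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(body) > 1L) {
    el <- utils::read.delim(text = paste(body, collapse = "\n"),
                            stringsAsFactors = FALSE)
    if (nrow(el)) A[cbind(match(el$from, ids), match(el$to, ids))] <- 1L
  }
  th <- suppressWarnings(as.numeric(getfield("threshold")))
  directed_network(A, kingdom = kingdom, leaf_id = getfield("leaf_id"),
                   treatment = getfield("treatment"), threshold = th)
}

#' Write / read a network as GraphML
#'
#' Nodes carry `kingdom` attributes; the graph carries `leaf_id`,
#' `treatment` and `threshold`.
#'
#' @param net a [directed_network()].
#' @param path GraphML path.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  g <- igraph::set_graph_attr(g, "leaf_id", as.character(net$leaf_id))
  g <- igraph::set_graph_attr(g, "treatment", as.character(net$treatment))
  g <- igraph::set_graph_attr(g, "threshold", as.numeric(net$threshold))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @return `read_graphml()` returns a [directed_network()].
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(A) <- list(igraph::V(g)$name, igraph::V(g)$name)
  kingdom <- if ("kingdom" %in% igraph::vertex_attr_names(g))
    stats::setNames(igraph::V(g)$kingdom, igraph::V(g)$name) else NULL
  ga <- function(key, cast = identity)
    if (key %in% igraph::graph_attr_names(g)) cast(igraph::graph_attr(g, key))
    else NA
  directed_network(A, kingdom = kingdom,
                   leaf_id = ga("leaf_id", as.character),
                   treatment = ga("treatment", as.character),
                   threshold = ga("threshold", as.numeric))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a study, computes overlap matrices, thresholds them
#' into competition networks, writes node/network/triad metrics, cross-group
#' comparisons and the higher-order-interaction randomization table, plus a
#' manifest recording every seed. Deterministic given the configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param params a [sim_params()] object used when `input` is `NULL`.
#' @param input optional path to a growth table CSV to analyse instead of
#'   simulating.
#' @param dialect growth-table dialect when reading `input`.
#' @param theta overlap cutoff for the binary networks.
#' @param n_rand randomizations per network for the HOI test; set
#'   `hoi = FALSE` to skip that stage.
#' @param hoi run the randomization test stage.
#' @param n_per_treatment,small_community passed to [generate_study()].
#' @param seed master seed.
#' @param correction multiple-testing correction method.
#' @return invisibly, a list with the study, overlap matrices, networks and
#'   result tables; all tables are also written under `out_dir`.
#' @export
run_pipeline <- function(out_dir, params = sim_params(), input = NULL,
                         dialect = "long", theta = 0.75, n_rand = 1000,
                         hoi = TRUE, n_per_treatment = 6,
                         small_community = FALSE, seed = params$seed,
                         correction = "BH") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- if (is.null(input)) {
    generate_study(params, n_per_treatment = n_per_treatment,
                   seed = seed, small_community = small_community)
  } else {
    read_growth_table(input, dialect = dialect)
  }
  write_growth_table(study, file.path(out_dir, "growth_long.csv"), "long")

  mats <- lapply(study, overlap_matrix)
  nets <- lapply(mats, threshold_network, theta = theta)
  for (leaf in names(mats)) {
    write_overlap_matrix(mats[[leaf]],
                         file.path(out_dir, sprintf("overlap_%s.csv", leaf)))
    write_edge_list(nets[[leaf]],
                    file.path(out_dir, sprintf("edges_%s.tsv", leaf)))
    write_graphml(nets[[leaf]],
                  file.path(out_dir, sprintf("network_%s.graphml", leaf)))
  }

  node_metrics <- do.call(rbind, lapply(nets, function(nt) {
    recs <- degree_records(nt)
    ids <- recs$isolate_id
    recs$leaf_id <- nt$leaf_id
    recs$treatment <- nt$treatment
    recs$degree_centrality <- recs$indegree + recs$outdegree
    recs$closeness_in <- vapply(ids, function(v)
      closeness_centrality(nt, v, "in"), numeric(1))
    recs$closeness_out <- vapply(ids, function(v)
      closeness_centrality(nt, v, "out"), numeric(1))
    recs$clustering <- vapply(ids, function(v)
      clustering_coefficient(nt, v), numeric(1))
    recs
  }))
  utils::write.csv(node_metrics, file.path(out_dir, "node_metrics.csv"),
                   row.names = FALSE)

  summaries <- do.call(rbind, lapply(nets, network_summary))
  utils::write.csv(summaries, file.path(out_dir, "network_summaries.csv"),
                   row.names = FALSE)

  census <- t(vapply(nets, triad_census, integer(16)))
  utils::write.csv(data.frame(leaf_id = rownames(census), census,
                              check.names = FALSE),
                   file.path(out_dir, "triad_census.csv"), row.names = FALSE)

  cmp_trt <- study_comparison(nets, "treatment", correction = correction)
  utils::write.csv(cmp_trt, file.path(out_dir, "comparison_treatment.csv"),
                   row.names = FALSE)
  cmp_kng <- study_comparison(nets, "kingdom", correction = correction)
  utils::write.csv(cmp_kng, file.path(out_dir, "comparison_kingdom.csv"),
                   row.names = FALSE)

  hoi_results <- NULL
  hoi_seeds <- NULL
  if (hoi) {
    hoi_seeds <- with_seed(seed + 1L,
      sample.int(.Machine$integer.max - 1L, length(nets)))
    hoi_results <- lapply(seq_along(nets), function(k)
      hoi_test(nets[[k]], n_rand = n_rand, seed = hoi_seeds[k]))
    names(hoi_results) <- names(nets)
    utils::write.csv(hoi_table(hoi_results),
                     file.path(out_dir, "hoi_table.csv"), row.names = FALSE)
  }

  manifest <- c(
    sprintf("overlapnet %s", as.character(utils::packageVersion("overlapnet"))),
    sprintf("R %s", as.character(getRversion())),
    sprintf("master_seed: %d", seed),
    sprintf("theta: %s", format(theta)),
    sprintf("n_rand: %d", as.integer(n_rand)),
    sprintf("correction: %s", correction),
    sprintf("communities: %s", paste(names(study), collapse = ",")),
    if (!is.null(hoi_seeds))
      sprintf("hoi_seeds: %s", paste(hoi_seeds, collapse = ","))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(study = study, overlap = mats, networks = nets,
                 node_metrics = node_metrics, summaries = summaries,
                 census = census, comparison_treatment = cmp_trt,
                 comparison_kingdom = cmp_kng, hoi = hoi_results))
}
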