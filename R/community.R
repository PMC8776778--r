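#' Construct a community table
#'
#' A community holds the resource-use profiles of co-occurring isolates from a
#' single leaf: a growth matrix (isolates x substrates, optical-density units)
#' plus kingdom labels and study metadata.
#'
#' @param growth numeric matrix, isolates x substrates, non-negative; rownames
#'   are isolate ids (generated if absent).
#' @param kingdom character vector, one of `"bacteria"`/`"fungi"` per isolate.
#' @param leaf_id single string identifying the leaf (community).
#' @param treatment `"control"` or `"NPK"`.
#' @return An object of class `community_table`: a list with elements
#'   `leaf_id`, `treatment`, `isolates` (data.frame of `isolate_id`,
#'   `kingdom`) and `growth`.
#' @export
community_table <- function(growth, kingdom, leaf_id, treatment) {
  growth <- as.matrix(growth)
  storage.mode(growth) <- "double"
  if (anyNA(growth)) stop("growth matrix contains missing values")
  if (any(growth < 0)) stop("growth values must be non-negative")
  m <- nrow(growth)
  if (m < 1L) stop("community must contain at least one isolate")
  if (length(kingdom) != m) stop("kingdom labels must match isolate count")
  kingdom <- match.arg(as.character(kingdom), c("bacteria", "fungi"),
                       several.ok = TRUE)
  if (length(kingdom) != m) stop("kingdom labels must match isolate count")
  treatment <- match.arg(treatment, c("control", "NPK"))
  if (is.null(rownames(growth))) {
    rownames(growth) <- sprintf("%s_iso%02d", leaf_id, seq_len(m))
  }
  if (anyDuplicated(rownames(growth))) stop("isolate ids must be unique")
  structure(
    list(
      leaf_id = as.character(leaf_id),
      treatment = treatment,
      isolates = data.frame(isolate_id = rownames(growth), kingdom = kingdom,
                            stringsAsFactors = FALSE),
      growth = growth
    ),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf(
    "community_table: leaf %s (%s), %d isolates (%d bacteria, %d fungi), %d substrates\n",
    x$leaf_id, x$treatment, nrow(x$growth),
    sum(x$isolates$kingdom == "bacteria"), sum(x$isolates$kingdom == "fungi"),
    ncol(x$growth)
  ))
  invisible(x)
}

#' Number of isolates in a community
#' @param community a `community_table`.
#' @return integer count.
#' @export
n_isolates <- function(community) nrow(community$growth)

#' Niche width of each isolate
#'
#' The niche width is the number of substrates on which an isolate shows
#' growth above `tol` (strictly greater).
#'
#' @param x a `community_table` or a non-negative growth matrix/vector.
#' @param tol non-negative growth threshold defining "non-zero growth";
#'   default 0, i.e. any positive optical density counts.
#' @return named integer vector (one entry for a single profile vector).
#' @export
niche_width <- function(x, tol = 0) {
  if (tol < 0) stop("tol must be non-negative")
  g <- if (inherits(x, "community_table")) x$growth else x
  if (is.null(dim(g))) {
    if (any(g < 0)) stop("growth values must be non-negative")
    return(sum(g > tol))
  }
  if (any(g < 0)) stop("growth values must be non-negative")
  rowSums(g > tol)
}
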