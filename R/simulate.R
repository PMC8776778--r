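#' Simulation parameters for synthetic endophyte communities
#'
#' Defaults emulate leaf-endophyte communities assayed on a 95-substrate
#' phenotype plate: ten bacteria and ten fungi per leaf, both kingdoms using
#' most substrates (fungi slightly more), fungi growing to higher optical
#' densities than bacteria (they are the dominant resource users), and an NPK
#' nutrient amendment that pulls fungal growth back toward bacterial levels
#' while making it more variable between fungal isolates.
#'
#' @param n_substrates number of carbon substrates on the plate (default 95).
#' @param n_bacteria,n_fungi isolates per kingdom per community.
#' @param niche_width_mean_bacteria,niche_width_mean_fungi expected number of
#'   usable substrates per isolate; widths are drawn per isolate from a
#'   binomial on `n_substrates` with this mean, truncated to
#'   `[1, n_substrates]`.
#' @param growth_scale baseline optical density on a usable substrate (OD
#'   units).
#' @param fungal_growth_advantage multiplier on `growth_scale` for fungal
#'   isolates; values > 1 make fungi the dominant resource users.
#' @param growth_dispersion lognormal sdlog of multiplicative plate-reader
#'   noise on growth values.
#' @param treatment_effect multiplier applied to fungal growth magnitudes
#'   under NPK (< 1 erodes the fungal advantage).
#' @param npk_heterogeneity sdlog of a per-fungal-isolate lognormal factor
#'   applied under NPK, making the treatment effect uneven across fungi.
#' @param seed default integer seed used by the generators when none is given.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_substrates = 95,
                       n_bacteria = 10,
                       n_fungi = 10,
                       niche_width_mean_bacteria = 85,
                       niche_width_mean_fungi = 90,
                       growth_scale = 0.5,
                       fungal_growth_advantage = 2.0,
                       growth_dispersion = 0.45,
                       treatment_effect = 0.6,
                       npk_heterogeneity = 0.3,
                       seed = 1L) {
  p <- list(
    n_substrates = as.integer(n_substrates),
    n_bacteria = as.integer(n_bacteria),
    n_fungi = as.integer(n_fungi),
    niche_width_mean_bacteria = niche_width_mean_bacteria,
    niche_width_mean_fungi = niche_width_mean_fungi,
    growth_scale = growth_scale,
    fungal_growth_advantage = fungal_growth_advantage,
    growth_dispersion = growth_dispersion,
    treatment_effect = treatment_effect,
    npk_heterogeneity = npk_heterogeneity,
    seed = as.integer(seed)
  )
  if (p$n_substrates < 1L || p$n_bacteria < 1L || p$n_fungi < 1L)
    stop("counts must be >= 1")
  for (w in c(p$niche_width_mean_bacteria, p$niche_width_mean_fungi)) {
    if (w < 1 || w > p$n_substrates)
      stop("niche width means must lie in [1, n_substrates]")
  }
  if (p$growth_scale <= 0) stop("growth_scale must be positive")
  if (p$growth_dispersion < 0) stop("growth_dispersion must be non-negative")
  if (p$fungal_growth_advantage <= 0) stop("fungal_growth_advantage must be positive")
  if (p$treatment_effect <= 0) stop("treatment_effect must be positive")
  if (p$npk_heterogeneity < 0) stop("npk_heterogeneity must be non-negative")
  structure(p, class = "sim_params")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic community
#'
#' Each isolate draws a niche width from a kingdom-specific binomial
#' (truncated to at least one substrate), picks that many usable substrates
#' uniformly without replacement, and grows on them with lognormal
#' (multiplicative) noise around its kingdom-specific scale. Under NPK the
#' growth of each fungal isolate is multiplied by
#' `treatment_effect * exp(N(0, npk_heterogeneity))`.
#'
#' @param params a [sim_params()] object.
#' @param leaf_id community identifier.
#' @param treatment `"control"` or `"NPK"`.
#' @param seed integer seed; the same seed always yields the identical
#'   community. `NULL` uses the current RNG stream.
#' @param n_bacteria override of `params$n_bacteria` (the study design allows
#'   one undersized leaf).
#' @return a [community_table()].
#' @export
generate_community <- function(params = sim_params(), leaf_id = "C1",
                               treatment = c("control", "NPK"),
                               seed = params$seed,
                               n_bacteria = params$n_bacteria) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  treatment <- match.arg(treatment)
  n_bacteria <- as.integer(n_bacteria)
  if (n_bacteria < 1L) stop("n_bacteria must be >= 1")
  with_seed(seed, {
    ns <- params$n_substrates
    kingdom <- rep(c("bacteria", "fungi"), c(n_bacteria, params$n_fungi))
    m <- length(kingdom)
    growth <- matrix(0, m, ns)
    ids <- sprintf("%s_%s%02d", leaf_id,
                   ifelse(kingdom == "bacteria", "b", "f"),
                   c(seq_len(n_bacteria), seq_len(params$n_fungi)))
    for (i in seq_len(m)) {
      wmean <- if (kingdom[i] == "bacteria") params$niche_width_mean_bacteria
               else params$niche_width_mean_fungi
      w <- stats::rbinom(1L, ns, wmean / ns)
      w <- max(1L, min(ns, w))
      usable <- sample.int(ns, w)
      scale_i <- params$growth_scale *
        (if (kingdom[i] == "fungi") params$fungal_growth_advantage else 1)
      if (treatment == "NPK" && kingdom[i] == "fungi") {
        scale_i <- scale_i * params$treatment_effect *
          stats::rlnorm(1L, 0, params$npk_heterogeneity)
      }
      growth[i, usable] <- stats::rlnorm(w, log(scale_i),
                                         params$growth_dispersion)
    }
    rownames(growth) <- ids
    community_table(growth, kingdom, leaf_id, treatment)
  })
}

#' Generate a full synthetic study
#'
#' Produces `2 * n_per_treatment` communities, half control (leaves
#' `C1..Ck`) and half NPK-amended (`N1..Nk`), with per-community seeds
#' derived from `seed` so the whole study is reproducible.
#'
#' @param params a [sim_params()] object.
#' @param n_per_treatment leaves per treatment (default 6, i.e. a
#'   twelve-community study).
#' @param seed master integer seed.
#' @param small_community if `TRUE`, the last control leaf gets only five
#'   bacterial isolates, exercising the unequal-community-size code path.
#' @return list of [community_table()] objects, named by leaf id.
#' @export
generate_study <- function(params = sim_params(), n_per_treatment = 6,
                           seed = params$seed, small_community = FALSE) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  n_per_treatment <- as.integer(n_per_treatment)
  if (n_per_treatment < 1L) stop("n_per_treatment must be >= 1")
  leaves <- c(sprintf("C%d", seq_len(n_per_treatment)),
              sprintf("N%d", seq_len(n_per_treatment)))
  treatments <- rep(c("control", "NPK"), each = n_per_treatment)
  seeds <- with_seed(seed,
    sample.int(.Machine$integer.max - 1L, length(leaves)))
  out <- vector("list", length(leaves))
  names(out) <- leaves
  for (k in seq_along(leaves)) {
    nb <- params$n_bacteria
    if (small_community && k == n_per_treatment) nb <- min(nb, 5L)
    out[[k]] <- generate_community(params, leaves[k], treatments[k],
                                   seed = seeds[k], n_bacteria = nb)
  }
  out
}
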