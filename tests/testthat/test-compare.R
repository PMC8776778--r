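test_that("Welch test matches hand-derived values and conventions", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p_raw, 0.0214, tolerance = 1e-2)
  # identical groups are never different
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_raw, 1)
  # equal means, unequal variances
  expect_equal(welch_t(c(2, 4), c(1, 3, 5))$t_stat, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch test is antisymmetric in group order", {
  set.seed(1)
  a <- rnorm(8); b <- rnorm(10, 0.5)
  r1 <- welch_t(a, b)
  r2 <- welch_t(b, a)
  expect_equal(r1$t_stat, -r2$t_stat)
  expect_equal(r1$p_raw, r2$p_raw)
})

test_that("BH adjustment matches the step-up rule and is order-invariant", {
  expect_equal(as.numeric(adjust_pvalues(0.03)), 0.03)
  expect_equal(as.numeric(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04))),
               rep(0.04, 4))
  expect_equal(as.numeric(adjust_pvalues(rep(1, 5))), rep(1, 5))
  set.seed(2)
  p <- runif(20)
  perm <- sample(20)
  adj <- as.numeric(adjust_pvalues(p))
  adj_perm <- as.numeric(adjust_pvalues(p[perm]))
  expect_equal(adj_perm[order(perm)], adj)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(adjust_pvalues(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("degree slope fits recover exact linear relations", {
  rec <- data.frame(kingdom = "bacteria", partner_filter = "all",
                    indegree = 10 - (0:5), outdegree = 0:5)
  f <- suppressWarnings(fit_degree_slope(rec))
  expect_equal(f$slope, -1)
  expect_equal(f$intercept, 10)
  rec2 <- data.frame(kingdom = "fungi", partner_filter = "all",
                     indegree = rep(4, 5), outdegree = 1:5)
  expect_equal(suppressWarnings(fit_degree_slope(rec2))$slope, 0)
  rec3 <- data.frame(kingdom = "fungi", partner_filter = "all",
                     indegree = c(4, 2, 0), outdegree = c(0, 1, 2))
  f3 <- suppressWarnings(fit_degree_slope(rec3))
  expect_equal(f3$slope, -2)
  expect_equal(f3$intercept, 4)
  # degenerate predictor is flagged, not fitted
  rec4 <- data.frame(kingdom = "fungi", partner_filter = "all",
                     indegree = 1:4, outdegree = rep(2, 4))
  f4 <- fit_degree_slope(rec4)
  expect_true(f4$degenerate)
  expect_true(is.na(f4$slope))
  expect_error(fit_degree_slope(rec3[1:2, ]), "at least 3")
})

test_that("community detection recovers planted modules", {
  # two disjoint complete directed 5-cliques
  A <- matrix(0L, 10, 10)
  A[1:5, 1:5] <- 1L
  A[6:10, 6:10] <- 1L
  diag(A) <- 0L
  net <- directed_network(A)
  dc <- detect_communities(net, seed = 3)
  expect_equal(length(unique(dc$membership)), 2)
  expect_equal(length(unique(dc$membership[1:5])), 1)
  expect_equal(length(unique(dc$membership[6:10])), 1)
  expect_gt(dc$modularity, 0.3)
  # complete graph: no modular structure
  Af <- matrix(1L, 8, 8); diag(Af) <- 0L
  dcf <- detect_communities(directed_network(Af), seed = 3)
  expect_equal(length(unique(dcf$membership)), 1)
  # determinism under seed
  dc2 <- detect_communities(net, seed = 3)
  expect_identical(dc$membership, dc2$membership)
})

test_that("planted two-block networks are recovered", {
  set.seed(15)
  n <- 20
  block <- rep(1:2, each = 10)
  P <- ifelse(outer(block, block, "=="), 0.9, 0.05)
  A <- matrix(rbinom(n * n, 1, as.vector(P)), n, n)
  diag(A) <- 0L
  net <- directed_network(A)
  dc <- detect_communities(net, seed = 21)
  # partition agrees with the planted blocks (up to label switching)
  tab <- table(dc$membership, block)
  expect_equal(sum(apply(tab, 1, max)), n)
  expect_equal(length(unique(dc$membership)), 2)
})

test_that("kingdom association chi-squared matches closed forms", {
  king <- setNames(rep(c("bacteria", "fungi"), each = 10), paste0("i", 1:20))
  # perfectly separated 10/10 two-module partition
  memb <- setNames(rep(c(1L, 2L), each = 10), names(king))
  ka <- kingdom_association(memb, king)
  expect_equal(ka$chi2, 20)
  # independence: balanced mixing gives chi2 0
  memb2 <- setNames(rep(c(1L, 2L), 10), names(king))
  ka2 <- kingdom_association(memb2, king)
  expect_equal(ka2$chi2, 0, tolerance = 1e-10)
  # single module: not applicable
  ka3 <- kingdom_association(setNames(rep(1L, 20), names(king)), king)
  expect_equal(ka3$method, "not-applicable")
  expect_true(is.na(ka3$p))
})

test_that("Monte-Carlo and asymptotic chi-squared p agree on large tables", {
  # large balanced table with a moderate association (chi2 ~ 3.2)
  tab <- as.table(rbind(c(540, 460), c(460, 540)))
  asym <- suppressWarnings(chisq.test(tab, correct = FALSE))
  mc <- with(list(), {
    set.seed(33)
    suppressWarnings(chisq.test(tab, correct = FALSE,
                                simulate.p.value = TRUE, B = 10000))
  })
  expect_lt(abs(asym$p.value - mc$p.value), 0.02)
})

test_that("study comparisons group correctly and mark absent triads", {
  set.seed(25)
  st <- generate_study(seed = 25)
  nets <- lapply(lapply(st, overlap_matrix), threshold_network)
  cmp <- study_comparison(nets, "treatment")
  expect_setequal(unique(cmp$family), c("global_metrics", "triad_counts"))
  expect_equal(sum(cmp$family == "triad_counts"), 16)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw - 1e-12, na.rm = TRUE))
  # triads absent in every network of both groups are not testable
  absent <- cmp$family == "triad_counts" & is.na(cmp$p_raw)
  if (any(absent)) {
    census <- t(vapply(nets, triad_census, integer(16)))
    cls <- sub("triad_", "", cmp$metric[absent])
    expect_true(all(colSums(census[, cls, drop = FALSE]) == 0))
  }
  kng <- study_comparison(nets, "kingdom")
  expect_equal(nrow(kng), 4 * 12)
  expect_true(all(kng$leaf_id %in% names(st)))
})

test_that("identical groups of networks yield p = 1 everywhere", {
  set.seed(26)
  base <- random_net(10, 0.4)
  nets <- list()
  for (k in 1:3) {
    a <- base; a$treatment <- "control"; a$leaf_id <- paste0("C", k)
    b <- base; b$treatment <- "NPK"; b$leaf_id <- paste0("N", k)
    nets <- c(nets, list(a, b))
  }
  cmp <- study_comparison(nets, "treatment", exclude_undersized = FALSE)
  expect_true(all(cmp$p_raw[!is.na(cmp$p_raw)] == 1))
})
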