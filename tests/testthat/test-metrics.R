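test_that("degree records respect partner-kingdom filters", {
  # 2 bacteria + 2 fungi, complete one-way bacteria -> fungi
  nodes <- c("b1", "b2", "f1", "f2")
  king <- setNames(c("bacteria", "bacteria", "fungi", "fungi"), nodes)
  net <- net_from_edges(nodes, list(c("b1", "f1"), c("b1", "f2"),
                                    c("b2", "f1"), c("b2", "f2")), king)
  cross <- degree_records(net, "cross_kingdom")
  expect_equal(cross$indegree[cross$kingdom == "fungi"], c(2, 2))
  expect_equal(cross$outdegree[cross$kingdom == "fungi"], c(0, 0))
  same <- degree_records(net, "same_kingdom")
  expect_true(all(same$indegree == 0) && all(same$outdegree == 0))
  expect_true(all(is.na(same$prop_in)))
  # empty network: all degrees zero, prop_in undefined
  empty <- net_from_edges(nodes, list(), king)
  rec <- degree_records(empty)
  expect_true(all(rec$indegree == 0) && all(is.na(rec$prop_in)))
  # complete directed graph: in = out = n - 1, prop_in = 1/2
  A <- matrix(1L, 20, 20); diag(A) <- 0L
  full <- directed_network(A)
  recf <- degree_records(full)
  expect_true(all(recf$indegree == 19) && all(recf$prop_in == 0.5))
  expect_error(degree_records(net, "nope"))
})

test_that("edge bookkeeping: total in equals total out equals edge count", {
  set.seed(21)
  for (r in 1:20) {
    net <- random_net(sample(3:10, 1), runif(1, 0.1, 0.6))
    rec <- degree_records(net)
    expect_equal(sum(rec$indegree), n_edges(net))
    expect_equal(sum(rec$outdegree), n_edges(net))
  }
})

test_that("distribution summary matches hand-computed moments", {
  s <- summarize_distribution(c(3, 3, 3))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 0)
  expect_true(is.na(s$skewness))
  expect_equal(summarize_distribution(c(1, 2, 3))$skewness, 0)
  # {0,0,1}: g1 = (2/27) / (2/9)^(3/2) = 1/sqrt(2)
  expect_equal(summarize_distribution(c(0, 0, 1))$skewness, 1 / sqrt(2))
  expect_error(summarize_distribution(numeric(0)), "no values")
})

test_that("degree centrality counts both link directions", {
  net <- net_from_edges(c("a", "b", "c"), list(c("a", "b"), c("b", "a")))
  expect_equal(degree_centrality(net, "a"), 2)  # reciprocal pair counts twice
  expect_equal(degree_centrality(net, "c"), 0)  # isolated
  A <- matrix(1L, 6, 6); diag(A) <- 0L
  expect_equal(degree_centrality(directed_network(A), "v01"), 10)  # 2(n-1)
  expect_error(degree_centrality(net, "zz"), "unknown node")
})

test_that("harmonic closeness on a directed path matches hand BFS", {
  net <- net_from_edges(c("a", "b", "c"),
                        list(c("a", "b"), c("b", "c")))
  expect_equal(closeness_centrality(net, "a", "out"), (1 + 1 / 2) / 2)
  expect_equal(closeness_centrality(net, "a", "in"), 0)
  A <- matrix(1L, 5, 5); diag(A) <- 0L
  full <- directed_network(A)
  expect_equal(closeness_centrality(full, "v03", "out"), 1)
  expect_equal(closeness_centrality(full, "v03", "in"), 1)
})

test_that("local clustering follows the undirected collapse", {
  tri <- net_from_edges(c("a", "b", "c"),
                        list(c("a", "b"), c("b", "c"), c("c", "a")))
  for (v in c("a", "b", "c"))
    expect_equal(clustering_coefficient(tri, v), 1)
  star <- net_from_edges(c("h", "x", "y", "z"),
                         list(c("h", "x"), c("h", "y"), c("h", "z")))
  expect_equal(clustering_coefficient(star, "h"), 0)
  expect_true(is.na(clustering_coefficient(star, "x")))  # degree 1
})

test_that("intransitivity separates hierarchies from cycles", {
  tt <- net_from_edges(c("a", "b", "c"),
                       list(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(intransitivity(tt), 0)
  cyc <- net_from_edges(c("a", "b", "c"),
                        list(c("a", "b"), c("b", "c"), c("c", "a")))
  expect_equal(intransitivity(cyc), 1)
  A <- matrix(1L, 3, 3); diag(A) <- 0L
  expect_equal(intransitivity(directed_network(A)), 0)  # all 2-paths closed
  expect_true(is.na(intransitivity(net_from_edges(c("a", "b"), list()))))
})

test_that("triad census counts the standard 16 classes", {
  empty <- directed_network(matrix(0L, 20, 20))
  tc <- triad_census(empty)
  expect_equal(unname(tc["003"]), choose(20, 3))
  expect_equal(sum(tc[-1]), 0)
  cyc <- net_from_edges(c("a", "b", "c"),
                        list(c("a", "b"), c("b", "c"), c("c", "a")))
  expect_equal(unname(triad_census(cyc)["030C"]), 1)
  expect_error(triad_census(net_from_edges(c("a", "b"), list())), "at least 3")
})

test_that("census conserves triples and edges on random graphs", {
  set.seed(99)
  for (r in 1:25) {
    n <- sample(4:9, 1)
    net <- random_net(n, runif(1, 0.1, 0.7))
    tc <- triad_census(net)
    expect_equal(sum(tc), choose(n, 3))
    # each class's edge count, times class count, recovers total edges
    edges_per_class <- c(0, 1, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 5, 6)
    expect_equal(sum(edges_per_class * tc) / (n - 2), n_edges(net))
  }
})

test_that("network summary assembles consistent global metrics", {
  A <- matrix(1L, 4, 4); diag(A) <- 0L
  s <- network_summary(directed_network(A))
  expect_equal(s$connectance, 1)
  expect_equal(s$mean_clustering, 1)
  empty <- directed_network(matrix(0L, 4, 4))
  se <- network_summary(empty)
  expect_equal(se$connectance, 0)
  expect_true(is.na(se$mean_clustering))
  tt <- net_from_edges(c("a", "b", "c"),
                       list(c("a", "b"), c("b", "c"), c("a", "c")))
  st <- network_summary(tt)
  expect_equal(st$connectance, 0.5)
  expect_equal(st$intransitivity, 0)
})
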