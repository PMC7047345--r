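test_that("reciprocal-weight distances match hand computation on toys", {
  expect_equal(unname(shortest_path_lengths(triangle())),
               matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  # path A-B-C with w = 0.5: each hop has length 2, so d(A,C) = 4
  d <- shortest_path_lengths(path_abc(0.5))
  expect_equal(d[1, 3], 4)
  # two disjoint edges: cross-component distances infinite
  w <- sym_graph(4, list(c(1, 2, 1), c(3, 4, 1)))
  d2 <- shortest_path_lengths(w)
  expect_true(all(is.infinite(d2[1:2, 3:4])))
})

test_that("Lp and NLp average finite distances and report disconnection", {
  d <- nodal_shortest_path(path_abc())
  expect_equal(unname(d), c(1.5, 1, 1.5))
  expect_equal(characteristic_path_length(path_abc())$Lp, 4 / 3)
  expect_equal(characteristic_path_length(complete_graph(5))$Lp, 1)

  w <- sym_graph(4, list(c(1, 2, 1), c(3, 4, 1)))
  cp <- characteristic_path_length(w)
  expect_equal(cp$infinite_pairs, 8)
  expect_equal(cp$Lp, 1)
  expect_warning(nodal_shortest_path(star_k(2) * 0), "NLp undefined")
})

test_that("adding an edge never increases any finite distance", {
  set.seed(31)
  for (rep in 1:20) {
    w <- random_weighted_graph(6)
    d0 <- shortest_path_lengths(w)
    off <- which(upper.tri(w) & w == 0)
    if (!length(off)) next
    e <- sample(off, 1)
    w2 <- w; w2[e] <- 0.9; w2 <- pmax(w2, t(w2))
    d1 <- shortest_path_lengths(w2)
    expect_true(all(d1 <= d0 + 1e-12))
  }
})

test_that("Onnela clustering handles toys and max-normalization", {
  expect_equal(clustering_coefficient(triangle(0.4, 0.4, 0.4)), 1)
  expect_equal(clustering_coefficient(star_k(3)), 0)
  # triangle with weights (w, w, w/8): the node whose incident edges are the
  # two strong ones has clustering (1 * 1 * 1/8)^(1/3) = 0.5
  cc <- clustering_coefficient(triangle(0.8, 0.8, 0.1), per_node = TRUE)
  expect_equal(unname(cc[1]), 0.5)
})

test_that("efficiencies match enumeration on toys", {
  expect_equal(global_efficiency(complete_graph(4)), 1)
  en <- nodal_efficiency(path_abc())
  expect_equal(unname(en), c(0.75, 1, 0.75))
  expect_equal(global_efficiency(path_abc()), mean(c(0.75, 1, 0.75)))
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_equal(local_efficiency(complete_graph(4)), 1)
  expect_equal(local_efficiency(star_k(4)), 0)
})

test_that("local efficiency equals explicit neighbor-subgraph recomputation", {
  # triangle plus pendant path, then random graphs
  w <- sym_graph(5, list(c(1, 2, 0.9), c(1, 3, 0.8), c(2, 3, 0.7),
                         c(3, 4, 0.6), c(4, 5, 0.5)))
  expect_equal(local_efficiency(w), oracle_local_efficiency(w), tolerance = 1e-9)
  set.seed(7)
  for (rep in 1:10) {
    w <- random_weighted_graph(sample(4:7, 1))
    expect_equal(local_efficiency(w), oracle_local_efficiency(w),
                 tolerance = 1e-9)
  }
})

test_that("betweenness credits tied shortest paths fractionally", {
  expect_equal(unname(betweenness_centrality(path_abc())), c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(star_k(4)))[1], 6)  # C(4,2)
  ring4 <- sym_graph(4, list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 1, 1)))
  expect_equal(unname(betweenness_centrality(ring4)), rep(0.5, 4))
})

test_that("degree centrality obeys the handshake lemma", {
  expect_equal(unname(degree_centrality(star_k(4))), c(4, 1, 1, 1, 1))
  expect_equal(unname(degree_centrality(matrix(0, 3, 3))), c(0, 0, 0))
  set.seed(9)
  w <- random_weighted_graph(7)
  expect_equal(sum(degree_centrality(w)), 2 * sum(w[upper.tri(w)] > 0))
})

test_that("distances, betweenness and efficiencies match brute force on small graphs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    w <- random_weighted_graph(n, p = runif(1, 0.4, 0.9))
    expect_equal(unname(shortest_path_lengths(w)), oracle_distances(w),
                 tolerance = 1e-9)
    expect_equal(unname(betweenness_centrality(w)), oracle_betweenness(w),
                 tolerance = 1e-9)
    expect_equal(unname(nodal_efficiency(w)), oracle_nodal_efficiency(w),
                 tolerance = 1e-9)
    # independent library cross-check for the distance table
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(unname(shortest_path_lengths(w)),
                 unname(igraph::distances(g, weights = 1 / igraph::E(g)$weight)),
                 tolerance = 1e-9)
  }
})

test_that("unit weights reduce every metric to its binary counterpart", {
  set.seed(55)
  w <- (random_weighted_graph(7) > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
  expect_equal(unname(shortest_path_lengths(w)),
               unname(igraph::distances(g)), tolerance = 1e-12)
  cc_bin <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  expect_equal(unname(clustering_coefficient(w, per_node = TRUE)), cc_bin,
               tolerance = 1e-12)
  expect_equal(unname(betweenness_centrality(w)),
               unname(igraph::betweenness(g)), tolerance = 1e-12)
})

test_that("metrics scale correctly under weight rescaling", {
  set.seed(77)
  w <- random_weighted_graph(7)
  cfac <- 0.37
  w2 <- w * cfac
  expect_equal(characteristic_path_length(w2)$Lp,
               characteristic_path_length(w)$Lp / cfac, tolerance = 1e-12)
  expect_equal(nodal_shortest_path(w2), nodal_shortest_path(w) / cfac,
               tolerance = 1e-12)
  expect_equal(global_efficiency(w2), global_efficiency(w) * cfac,
               tolerance = 1e-12)
  expect_equal(clustering_coefficient(w2), clustering_coefficient(w),
               tolerance = 1e-12)
  expect_equal(degree_centrality(w2), degree_centrality(w))
  expect_equal(betweenness_centrality(w2), betweenness_centrality(w),
               tolerance = 1e-9)
})

test_that("AUC is the trapezoidal integral and is exact for linear curves", {
  s <- seq(0.05, 0.5, 0.05)
  expect_equal(metric_auc(s, rep(1, 10)), 0.45)
  vals <- 2 + 3 * s                       # integral of 2+3s over [0.05, 0.5]
  expect_equal(metric_auc(s, vals), 2 * 0.45 + 1.5 * (0.5^2 - 0.05^2))
  expect_error(metric_auc(s, 1:3), "lengths differ")
  expect_error(metric_auc(c(0.1, 0.1), c(1, 2)), "strictly increasing")
})
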