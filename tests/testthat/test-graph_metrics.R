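test_that("degree, density and average degree on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  expect_true(all(degree_centrality(k4) == 3))
  expect_equal(graph_density(k4), 1.0)
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  d <- degree_centrality(star)
  expect_equal(unname(d[1]), 4L)
  expect_true(all(d[-1] == 1))
  expect_equal(graph_density(igraph::make_empty_graph(5, directed = FALSE)), 0)
  p3 <- igraph::make_ring(3, circular = FALSE)
  expect_equal(graph_density(p3), 2 / 3)
  expect_error(graph_density(igraph::make_empty_graph(1, directed = FALSE)),
               "fewer than 2")
  # degree sum identity 2|E| on random graphs
  set.seed(5)
  for (i in 1:10) {
    g <- random_gnp_named(20, 0.2)
    expect_equal(sum(degree_centrality(g)), 2 * igraph::ecount(g))
    expect_equal(average_degree(g), 2 * igraph::ecount(g) / 20)
    A <- adj_dense(g)
    expect_equal(unname(degree_centrality(g)), unname(rowSums(A)))
  }
})

test_that("component census covers canonical and random cases", {
  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  expect_identical(graph_components(two_tri)$census, c(3L, 3L))
  conn <- igraph::make_full_graph(7)
  expect_identical(graph_components(conn)$census, 7L)
  set.seed(11)
  for (i in 1:10) {
    g <- random_gnp_named(100, 0.012)
    mine <- graph_components(g)$membership
    oracle <- oracle_components(g)
    # same partition up to label names: co-membership must agree
    expect_true(all((outer(mine, mine, `==`) == outer(oracle, oracle, `==`))))
    expect_identical(sum(graph_components(g)$census), 100L)
  }
})

test_that("distance statistics match Floyd-Warshall on paths and random graphs", {
  p10 <- igraph::make_ring(10, circular = FALSE)
  ds <- distance_stats(p10)
  expect_equal(ds$diameter, 9L)
  p3 <- igraph::make_ring(3, circular = FALSE)
  expect_equal(distance_stats(p3)$average_distance, 4 / 3)
  expect_error(distance_stats(igraph::make_empty_graph(4, directed = FALSE)),
               "no edges")
  set.seed(21)
  for (i in 1:8) {
    g <- random_gnp_named(30, 0.12)
    if (igraph::ecount(g) == 0) next
    D <- oracle_floyd_warshall(adj_dense(g))
    up <- D[upper.tri(D)]
    fin <- up[is.finite(up)]
    ds <- distance_stats(g)
    expect_equal(ds$average_distance, mean(fin))
    expect_equal(ds$diameter, as.integer(max(fin)))
    expect_equal(ds$n_pairs, length(fin))
  }
})

test_that("clustering coefficients match triple enumeration; convention options", {
  tri <- igraph::make_full_graph(3)
  cl <- clustering_coefficients(tri)
  expect_true(all(cl$local == 1))
  expect_equal(cl$global_C, 1)
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(clustering_coefficients(star)$global_C, 0)
  set.seed(31)
  for (i in 1:8) {
    g <- random_gnp_named(25, 0.25)
    cl <- clustering_coefficients(g)
    expect_equal(unname(cl$local), oracle_clustering(g))
    # exclusion convention averages over deg >= 2 only
    deg <- degree_centrality(g)
    if (any(deg >= 2) && any(deg < 2)) {
      cl2 <- clustering_coefficients(g, include_low_degree = FALSE)
      expect_equal(cl2$global_C, mean(oracle_clustering(g)[deg >= 2]))
      expect_gte(cl2$global_C, cl$global_C)
    }
  }
})

test_that("betweenness matches exhaustive path-count oracle", {
  p3 <- igraph::make_ring(3, circular = FALSE)
  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))
  k5 <- igraph::make_full_graph(5)
  expect_true(all(betweenness_centrality(k5) == 0))
  c5 <- igraph::make_ring(5)
  expect_true(all(abs(betweenness_centrality(c5) - 1) < 1e-12))
  set.seed(41)
  for (i in 1:10) {
    g <- random_gnp_named(sample(6:18, 1), 0.3)
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(g),
                 tolerance = 1e-12)
  }
})

test_that("pagerank solves the damped random-walk fixed point", {
  c6 <- igraph::make_ring(6)
  expect_equal(unname(pagerank_centrality(c6)), rep(1 / 6, 6),
               tolerance = 1e-8)
  k5 <- igraph::make_full_graph(5)
  expect_equal(unname(pagerank_centrality(k5)), rep(1 / 5, 5),
               tolerance = 1e-8)
  # asymmetric graph vs direct linear solve
  g <- igraph::graph_from_edgelist(
    cbind(c(1, 1, 2, 3, 4), c(2, 3, 3, 4, 5)), directed = FALSE)
  g <- igraph::add_vertices(g, 1)  # isolated node 6
  pr <- pagerank_centrality(g, tolerance = 1e-13)
  expect_equal(unname(pr), oracle_pagerank(g), tolerance = 1e-9)
  expect_equal(sum(pr), 1, tolerance = 1e-8)
  set.seed(51)
  for (i in 1:8) {
    gg <- random_gnp_named(25, 0.15)
    pr <- pagerank_centrality(gg, tolerance = 1e-13)
    expect_equal(sum(pr), 1, tolerance = 1e-8)
    expect_equal(unname(pr), oracle_pagerank(gg), tolerance = 1e-9)
  }
  expect_error(pagerank_centrality(c6, damping = 1.2), "damping")
  expect_error(pagerank_centrality(c6, tolerance = 0, max_iter = 3),
               "no convergence")
})

test_that("modularity formula: single community zero, split cliques one half", {
  g <- random_gnp_named(20, 0.3)
  expect_equal(modularity_q(g, rep(1, 20)), 0)
  cl2 <- igraph::disjoint_union(igraph::make_full_graph(6),
                                igraph::make_full_graph(6))
  expect_equal(modularity_q(cl2, rep(1:2, each = 6)), 0.5)
  expect_error(modularity_q(igraph::make_empty_graph(3, directed = FALSE),
                            rep(1, 3)), "edgeless")
  # never exceeds 1 on random partitions
  set.seed(61)
  for (i in 1:10) {
    gg <- random_gnp_named(15, 0.3)
    if (igraph::ecount(gg) == 0) next
    expect_lte(modularity_q(gg, sample(1:4, 15, replace = TRUE)), 1)
  }
})

test_that("community detection reaches the planted two-block modularity", {
  g <- generate_sbm_graph(c(20, 20), p_in = 0.5, p_out = 0.02, seed = 77)
  part <- detect_communities(g, seed = 20140328)
  planted_q <- modularity_q(g, igraph::V(g)$block)
  expect_gte(part$modularity, planted_q - 0.01)
  # reported Q is consistent with the modularity function
  expect_equal(part$modularity, modularity_q(g, part$membership))
  # deterministic under fixed seed
  part2 <- detect_communities(g, seed = 20140328)
  expect_identical(part$membership, part2$membership)
  cl2 <- igraph::disjoint_union(igraph::make_full_graph(6),
                                igraph::make_full_graph(6))
  pc <- detect_communities(cl2)
  expect_equal(pc$modularity, 0.5)
  expect_equal(max(pc$membership), 2L)
})

test_that("power-law MLE recovers known exponents and fails on degenerates", {
  d <- sample_power_law_degrees(2.5, 1, 1e5, seed = 101)
  f <- fit_power_law(d, xmin = 1)
  expect_false(f$failed)
  expect_lt(abs(f$alpha - 2.5), 0.05)
  d3 <- sample_power_law_degrees(3.0, 1, 1e4, seed = 102)
  f3 <- fit_power_law(d3, xmin = 1)
  expect_lt(abs(f3$alpha - 3.0), 0.1)
  # degenerate inputs give explicit failures, not errors
  expect_true(fit_power_law(rep(3L, 100))$failed)
  expect_true(fit_power_law(c(1L, 2L, 3L))$failed)
  # auto-xmin on clean data stays near the true threshold
  fa <- fit_power_law(d)
  expect_false(fa$failed)
  expect_lte(fa$xmin, 3L)
  expect_lt(abs(fa$alpha - 2.5), 0.08)
  expect_gte(fa$n_tail, 50L)
})

test_that("power-law MLE is unbiased within 0.03 over repeated seeds", {
  errs <- vapply(1:12, function(s) {
    d <- sample_power_law_degrees(2.5, 1, 1e5, seed = 5000 + s)
    abs(fit_power_law(d, xmin = 1)$alpha - 2.5)
  }, numeric(1))
  expect_lt(mean(errs), 0.03)
})

test_that("author ranking orders by metric with deterministic tie-breaks", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("center", "w", "x", "y", "z")
  igraph::V(star)$income_group <- c("high", "low", "low", "middle", "high")
  r <- rank_authors(star, "degree", top_k = 1)
  expect_identical(r$name, "center")
  expect_identical(r$income_group, "high")
  p3 <- igraph::make_ring(3, circular = FALSE)
  igraph::V(p3)$name <- c("a", "mid", "b")
  expect_identical(rank_authors(p3, "betweenness", top_k = 1)$name, "mid")
  # order agrees with an oracle sort of oracle-computed values
  set.seed(71)
  g <- random_gnp_named(60, 0.1)
  r <- rank_authors(g, "betweenness", top_k = 60)
  oracle <- oracle_betweenness(g)
  names(oracle) <- igraph::V(g)$name
  expected <- names(oracle)[order(-oracle, names(oracle))]
  expect_identical(r$name, expected)
  expect_error(rank_authors(g, "closeness"), "arg")
})
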