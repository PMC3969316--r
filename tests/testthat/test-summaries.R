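tab <- test_income_table()

test_that("collaboration-size table bins authors and countries per record", {
  corp <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "USA", "C, C" = "USA"))))
  t1 <- collaboration_size_table(corp)
  expect_equal(t1$authors_pct[t1$size == "3"], 100)
  expect_equal(t1$countries_pct[t1$size == "1"], 100)
  # 15+ pooling
  big <- bib_corpus(list(make_record("big", stats::setNames(
    lapply(1:20, function(i) "USA"), sprintf("A%02d, X", 1:20)))))
  tb <- collaboration_size_table(big)
  expect_equal(tb$authors_n[tb$size == "15+"], 1L)
  # empty corpus -> zero totals
  t0 <- collaboration_size_table(bib_corpus(list()))
  expect_true(all(t0$authors_n == 0) && all(t0$countries_n == 0))
})

test_that("size-table percentages recompute exactly from the counts", {
  for (seed in c(3, 12)) {
    corp <- random_corpus(40, seed = seed)
    t1 <- collaboration_size_table(corp)
    expect_equal(t1$authors_pct,
                 round_half_up(100 * t1$authors_n / sum(t1$authors_n), 1))
    expect_equal(t1$countries_pct,
                 round_half_up(100 * t1$countries_n / sum(t1$countries_n), 1))
    expect_equal(sum(t1$authors_n), length(corp))
    expect_lt(abs(sum(t1$authors_pct) - 100), 0.3)
  }
})

test_that("income-extremes labelling follows the max/min rule", {
  expect_identical(classify_income_extremes(c("USA", "BRA", "ZAF"), tab),
                   "high-middle")
  expect_identical(classify_income_extremes(c("UGA", "KEN"), tab), "low-low")
  expect_identical(classify_income_extremes(c("UGA", "BRA", "USA"), tab),
                   "high-low")
  expect_identical(classify_income_extremes(c("USA", "XXX"), tab),
                   "unclassified")
  expect_error(classify_income_extremes("USA", tab), ">= 2")
  # invariance under duplication (set semantics) and full enumeration of the
  # extremes rule over all non-empty level subsets
  lv <- list(low = "UGA", middle = "BRA", high = "USA")
  for (subset in list(c("low", "middle"), c("low", "high"),
                      c("middle", "high"), c("low", "middle", "high"))) {
    cs <- unlist(lv[subset])
    lab <- classify_income_extremes(cs, tab)
    expected <- paste(subset[length(subset)], subset[1], sep = "-")
    expect_identical(lab, expected)
    expect_identical(classify_income_extremes(rep(cs, 3), tab), lab)
  }
})

test_that("income-pairing table partitions international records", {
  corp <- mixed_fixture_corpus()
  ipt <- income_pairing_table(corp, tab)
  # r2 (USA,UGA,ZAF) -> high-low; r4 (UGA,KEN) -> low-low; r5 -> high-middle
  expect_equal(attr(ipt, "n_international"), 3L)
  expect_equal(ipt$frequency[ipt$pairing == "high-low"], 1L)
  expect_equal(ipt$frequency[ipt$pairing == "low-low"], 1L)
  expect_equal(ipt$frequency[ipt$pairing == "high-middle"], 1L)
  expect_equal(sum(ipt$frequency), 3L)
  # missing sample size excluded with reported denominator (r5 has none)
  expect_equal(ipt$n_sample_size[ipt$pairing == "high-middle"], 0L)
  expect_true(is.na(ipt$mean_sample_size[ipt$pairing == "high-middle"]))
  expect_equal(ipt$mean_sample_size[ipt$pairing == "high-low"], 400)
  # corpus with no international records -> all-zero table
  dom <- bib_corpus(list(make_record("d1", list("A, A" = "USA",
                                                "B, B" = "USA"))))
  expect_equal(sum(income_pairing_table(dom, tab)$frequency), 0L)
})

test_that("pairing frequencies partition across random corpora", {
  for (seed in c(7, 19)) {
    corp <- random_corpus(30, seed = seed)
    ipt <- income_pairing_table(corp, tab)
    intl <- vapply(corp, is_international, logical(1))
    expect_equal(sum(ipt$frequency), sum(intl, na.rm = TRUE))
  }
})

test_that("small-world verdict separates rewired lattices from random graphs", {
  # ring lattice with light rewiring: classic small-world construction
  g <- igraph::sample_smallworld(1, 100, 4, 0.05)
  g <- igraph::simplify(g)
  sw <- small_world_report(g, n_random = 8, seed = 5)
  expect_gt(sw$sigma, 1)
  expect_gt(sw$C_ratio, 2)
  expect_true(sw$small_world)
  # a uniform random graph compared with its own family: sigma near 1
  # (dense enough that the clustering ratio is statistically stable)
  set.seed(9)
  gr <- random_gnp_named(100, 0.15)
  gr <- largest_component(gr)
  swr <- small_world_report(gr, n_random = 10, seed = 6)
  expect_lt(abs(swr$sigma - 1), 0.25)
  expect_false(swr$small_world)
  # two cliques + bridge: clustering far above the random expectation
  gb <- igraph::disjoint_union(igraph::make_full_graph(12),
                               igraph::make_full_graph(12))
  gb <- igraph::add_edges(gb, c(1, 13))
  swb <- small_world_report(gb, n_random = 8, seed = 7)
  expect_gt(swb$C_ratio, 2)
  expect_error(small_world_report(g, n_random = 1), "n_random")
})

test_that("network statistics report aggregates consistently", {
  p10 <- igraph::make_ring(10, circular = FALSE)
  igraph::V(p10)$name <- letters[1:10]
  rep1 <- network_statistics_report(p10, include_spectral = FALSE)
  expect_equal(rep1$diameter, 9L)
  expect_equal(rep1$density, 2 * 9 / 90)
  expect_equal(rep1$global_clustering, 0)
  expect_equal(rep1$component_census, 10L)
  expect_equal(sum(rep1$component_census), rep1$n_nodes)
  expect_gte(rep1$diameter, rep1$average_distance)
  # determinism on a synthetic corpus graph
  corp <- generate_corpus(corpus_config(seed = 1, n_papers = 40))
  g <- build_author_network(corp, load_income_table())
  r1 <- network_statistics_report(g, seed = 99)
  r2 <- network_statistics_report(g, seed = 99)
  r1$nodes <- r2$nodes <- NULL
  expect_identical(r1, r2)
})
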