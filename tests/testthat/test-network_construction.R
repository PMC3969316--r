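tab <- test_income_table()

test_that("clique expansion builds the author network", {
  # one 3-author record -> triangle
  corp <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "USA", "C, C" = "USA"))))
  g <- build_author_network(corp, tab)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 3L)
  expect_true(all(igraph::E(g)$weight == 1L))
  # repeated pair -> aggregated weight
  corp2 <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "USA")),
    make_record("r2", list("A, A" = "USA", "B, B" = "USA"))))
  g2 <- build_author_network(corp2, tab)
  expect_equal(igraph::ecount(g2), 1L)
  expect_identical(igraph::E(g2)$weight, 2L)
  # disjoint records -> disjoint components; single-author record -> isolate
  corp3 <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "USA", "C, C" = "USA")),
    make_record("r2", list("D, D" = "UGA", "E, E" = "UGA")),
    make_record("r3", list("F, F" = "BRA"))))
  g3 <- build_author_network(corp3, tab)
  expect_identical(graph_components(g3)$census, c(3L, 2L, 1L))
})

test_that("author edge weights equal brute-force co-occurrence counts", {
  for (seed in c(4, 8, 15)) {
    corp <- random_corpus(25, seed = seed)
    g <- build_author_network(corp, tab)
    W <- oracle_cooccurrence(corp)
    expect_setequal(igraph::V(g)$name, rownames(W))
    el <- igraph::as_edgelist(g)
    for (e in seq_len(nrow(el))) {
      expect_identical(igraph::E(g)$weight[e], W[el[e, 1], el[e, 2]])
    }
    # no edge missing: total weight matches
    expect_equal(sum(igraph::E(g)$weight), sum(W) / 2)
  }
})

test_that("author income group is the modal country, ties to higher income", {
  corp <- bib_corpus(list(
    make_record("r1", list("A, A" = "UGA", "B, B" = "UGA")),
    make_record("r2", list("A, A" = "UGA", "C, C" = "USA")),
    make_record("r3", list("A, A" = "USA", "C, C" = "USA")),
    make_record("r4", list("D, D" = character(0), "B, B" = "UGA"))))
  g <- build_author_network(corp, tab)
  v <- igraph::V(g)
  # A appears with UGA twice, USA once -> modal UGA, low income
  expect_identical(v$income_group[v$name == "a, a"], "low")
  expect_false(v$income_tie[v$name == "a, a"])
  # D has no affiliation anywhere
  expect_identical(v$income_group[v$name == "d, d"], "unknown")
  # tie UGA/USA resolves to the higher income level and is flagged
  corp_tie <- bib_corpus(list(
    make_record("r1", list("E, E" = "UGA", "X, X" = "UGA")),
    make_record("r2", list("E, E" = "USA", "Y, Y" = "USA"))))
  gt <- build_author_network(corp_tie, tab)
  vt <- igraph::V(gt)
  expect_identical(vt$income_group[vt$name == "e, e"], "high")
  expect_true(vt$income_tie[vt$name == "e, e"])
})

test_that("country network counts record-level country pairs", {
  corp <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "UGA"))))
  g <- build_country_network(corp, tab)
  expect_setequal(igraph::V(g)$name, c("USA", "UGA"))
  expect_identical(igraph::E(g)$weight, 1L)
  # repeated pair aggregates
  corp2 <- bib_corpus(lapply(1:3, function(i)
    make_record(paste0("r", i), list("A, A" = "USA", "B, B" = "ZAF"))))
  g2 <- build_country_network(corp2, tab)
  expect_identical(igraph::E(g2)$weight, 3L)
  # triple-country record -> triangle of weight-1 edges (brute pair check)
  corp3 <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "UGA", "C, C" = "BRA"))))
  g3 <- build_country_network(corp3, tab)
  expect_equal(igraph::ecount(g3), 3L)
  expect_true(all(igraph::E(g3)$weight == 1L))
  pairs <- utils::combn(sort(c("USA", "UGA", "BRA")), 2)
  for (j in 1:3) {
    expect_true(igraph::are_adjacent(g3, pairs[1, j], pairs[2, j]))
  }
  # records without any affiliation country are skipped and counted
  corp4 <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "USA")),
    bib_record("r2", authors = list(author_ref("C, C")))))
  g4 <- build_country_network(corp4, tab)
  expect_identical(igraph::graph_attr(g4, "n_skipped_no_country"), 1L)
})

test_that("country-network weights are additive in records", {
  # merging two records with the identical country union leaves every
  # node's incident weight sum changed by exactly the duplicated increment
  corp_a <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "UGA")),
    make_record("r2", list("C, C" = "USA", "D, D" = "UGA"))))
  corp_b <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "UGA"))))
  ga <- build_country_network(corp_a, tab)
  gb <- build_country_network(corp_b, tab)
  wa <- sum(igraph::E(ga)$weight[igraph::E(ga) %in%
                                   igraph::incident(ga, "USA")])
  wb <- sum(igraph::E(gb)$weight[igraph::E(gb) %in%
                                   igraph::incident(gb, "USA")])
  expect_equal(wa, 2 * wb)
})

test_that("mixing matrix matches hand-enumerated group memberships", {
  corp <- mixed_fixture_corpus()
  M <- mixing_matrix(corp, tab)
  expect_true(isSymmetric(M))
  expect_true(all(M >= 0))
  # hand enumeration:
  # r1 {USA}            -> (high, high) diagonal
  # r2 {USA, UGA, ZAF}  -> pairs (high,low), (high,middle), (low,middle)
  # r3 {BRA}            -> (middle, middle) diagonal
  # r4 {UGA, KEN}       -> union all low -> (low, low) diagonal
  # r5 {USA, GBR, BRA}  -> (high, middle)
  expect_identical(M["high", "high"], 1L)
  expect_identical(M["middle", "middle"], 1L)
  expect_identical(M["low", "low"], 1L)
  expect_identical(M["high", "middle"], 2L)
  expect_identical(M["high", "low"], 1L)
  expect_identical(M["low", "middle"], 1L)
  expect_identical(M["unknown", "unknown"], 0L)
  # all-domestic corpus: diagonal only
  dom <- bib_corpus(lapply(1:4, function(i)
    make_record(paste0("d", i), list("A, A" = "USA", "B, B" = "USA"))))
  Md <- mixing_matrix(dom, tab)
  expect_identical(Md["high", "high"], 4L)
  expect_identical(sum(Md), 4L)
})

test_that("largest_component matches a union-find oracle", {
  corp <- bib_corpus(list(
    make_record("r1", list("A, A" = "USA", "B, B" = "USA", "C, C" = "USA",
                           "D, D" = "USA", "E, E" = "USA")),
    make_record("r2", list("X, X" = "UGA", "Y, Y" = "UGA", "Z, Z" = "UGA"))))
  g <- build_author_network(corp, tab)
  expect_equal(igraph::vcount(largest_component(g)), 5L)
  # identity on a connected graph
  gc <- igraph::make_full_graph(6)
  igraph::V(gc)$name <- letters[1:6]
  expect_equal(igraph::vcount(largest_component(gc)), 6L)
  # sparse random graphs vs oracle labelling
  set.seed(99)
  for (i in 1:10) {
    gr <- random_gnp_named(50, 0.03)
    memb <- oracle_components(gr)
    lc <- largest_component(gr)
    expect_equal(igraph::vcount(lc), max(tabulate(memb)))
    # the returned node set is exactly one maximal oracle component
    comp_of_first <- memb[match(igraph::V(lc)$name[1], igraph::V(gr)$name)]
    expect_setequal(igraph::V(lc)$name,
                    igraph::V(gr)$name[memb == comp_of_first])
  }
  expect_error(largest_component(igraph::make_empty_graph(0)), "empty")
})
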