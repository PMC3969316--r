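# coauthnet

Co-authorship network analysis of bibliographic corpora, with an emphasis
on *international* scientific collaboration between countries of different
World Bank income groups — the collaboration structure of HIV/HPV
co-infection epidemiology, where disease burden and research capacity sit
in different parts of the world.

## What it computes

From structured bibliographic records (year, title, journal, enrollment
count, enrollment countries, author list with per-author affiliation
countries), `coauthnet`:

* validates and normalizes the corpus (author identity by normalized name
  key; ISO 3166-1 alpha-3 country codes; three-level income
  classification with explicit `unknown`);
* builds weighted undirected **author** and **country** co-publication
  graphs by clique expansion, plus record-level income-group **mixing
  matrices**;
* computes the standard network statistics **from scratch** (igraph is
  used as a container and as an independent cross-check in the tests,
  never for the statistics themselves):
  degree centrality and average degree `2|E|/n`; density
  `2|E|/(n(n-1))`; connected components; average within-component
  distance `L` and diameter; local/global clustering coefficient `C`
  (mean-of-local convention); Brandes betweenness; PageRank (damping
  0.85); Newman–Girvan modularity `Q` and Louvain-style greedy community
  detection; discrete maximum-likelihood power-law exponent `α` of the
  degree distribution with KS-selected `xmin`;
* clusters the giant component with **Laplacian spectral clustering**
  (`L = D − A`, eigengap-selected k, seeded k-means on the embedding);
* produces the tabular summaries of the field: collaboration-size
  distributions, income-extreme pairing tables (a {high, middle, middle}
  collaboration is *high–middle*) with enrollment-count means, and a
  small-world assessment `σ = (C/C_rand)/(L/L_rand)` against matched
  uniform random graphs;
* generates **synthetic corpora** (seeded, reproducible) with the
  qualitative structure of the motivating study regime — 278 papers,
  ~1,200–1,350 authors, ~65% single-country studies, a ~70% giant
  component plus dozens of small components, mixed-extreme collaborations
  enrolling ~3× more participants — so the whole pipeline runs and is
  tested without any external dataset.

See `vignettes/collaboration-networks.Rmd` for the conventions behind each
statistic (they differ across tools by factors of two) and the design of
the generator.

## Worked example

```r
library(coauthnet)

income <- load_income_table()                      # packaged income table
corpus <- generate_corpus(corpus_config(seed = 1)) # 278 synthetic papers
corpus
#> <bib_corpus 'synthetic(seed=1)': 278 records, 1203 distinct authors>

g <- build_author_network(corpus, income)
network_statistics_report(g, include_betweenness = FALSE, seed = 1)
#> <metrics_report: 1203 nodes, 9186 edges>
#>   average degree 15.27, density 0.0127
#>   clustering C = 0.736, average distance L = 3.22, diameter 6
#>   components: 42 (giant 72.7%), modularity Q = 0.787
#>   degree power law: alpha = 5.73 (xmin 27, n_tail 179)
#>   spectral clusters (giant component): k = 2, census [535, 340]

rank_authors(g, "degree", top_k = 3)
#>   rank         name value income_group metric
#> 1    1 core02, a017    61         high degree
#> 2    2 core04, a096    56       middle degree
#> 3    3 core07, a015    55         high degree

small_world_report(largest_component(g), n_random = 10, seed = 1)
#> <small_world_report: C = 0.637 (rand 0.021), L = 3.23 (rand 2.66), sigma = 25.41 -> small-world>
```

Reading: the synthetic corpus produces a sparse (density 0.013), highly
clustered (C = 0.74 vs 0.02 for a matched random graph) author network
with short paths — the small-world signature of collaboration networks —
whose giant component holds 72.7% of the 1,203 authors, with modular
community structure (Q = 0.79). Rankings annotate each author with the
income group of their modal affiliation country. (The steep fitted tail
exponent reflects the community-reuse mechanism of the generator, not a
calibrated degree distribution; exact power-law recovery is exercised via
`sample_power_law_degrees()`.)

`run_pipeline(pipeline_config(output_dir = "out", seed = 1))` executes the
whole chain and writes GraphML/GEXF/TSV graphs, TSV/Markdown tables, JSON
reports and a manifest; reruns with the same config are byte-identical.

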