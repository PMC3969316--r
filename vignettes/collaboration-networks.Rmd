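---
title: "Methods: co-authorship network analysis with coauthnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-authorship network analysis with coauthnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coauthnet)
```

## The analysis

`coauthnet` studies patterns of scientific collaboration in a corpus of
bibliographic records. The motivating domain is HIV/HPV co-infection
epidemiology, where the disease burden concentrates in low- and
middle-income countries while most researchers and funding sit in
high-income countries, so *international* collaboration structure — who
publishes with whom, across which income groups, and with what consequences
for study enrollment — is the scientific question.

The model of a collaboration is deliberately simple and standard:

* every paper with more than one author is a scientific collaboration;
* a paper whose authors are affiliated to institutions in **different
  countries** is an international collaboration (the union of the
  per-author affiliation country sets has two or more members);
* countries carry a World Bank style three-level income classification
  (low / middle / high, with the two middle sub-levels collapsed).

Two undirected co-publication graphs are built by clique expansion: an
**author network** (one node per author identity, one weight unit per
co-authored paper) and a **country network** (one node per affiliation
country, one weight unit per record linking two countries). Record-level
income-group **mixing matrices** cross-tabulate the same information at the
group level.

## Conventions behind each statistic

The reported statistics all have convention choices that change numbers by
factors of two or more; the package fixes them explicitly and exposes the
genuinely ambiguous ones as options.

* **Unweighted metrics.** Degree, distances, clustering, betweenness,
  PageRank, modularity all treat the graph as an unweighted simple graph:
  a degree of 11 means "collaborated with 11 distinct authors", regardless
  of how often. Edge weights (co-publication counts) are retained as
  attributes for export and edge-width rendering only.
* **Global clustering coefficient** is the *mean of the local
  coefficients*, not the transitivity (triangle/triple) ratio, and nodes of
  degree < 2 contribute 0 to the mean. This is the convention of common
  network-visualization tools and the only one that plausibly yields a
  global C near 0.9 on a sparse collaboration graph; the exclusion variant
  is available via `include_low_degree = FALSE`.
* **Average distance** is taken over unordered node pairs *within*
  components (a disconnected graph has no finite all-pairs mean); the
  diameter is the largest finite distance. `distance_stats(...,
  denominator = "giant")` restricts both to the largest component.
* **Betweenness** is unnormalized, endpoints excluded, each unordered pair
  counted once, fractional credit across equal-length geodesics — stated
  because conventions differ by a factor of 2.
* **PageRank** uses damping 0.85, L1 tolerance 1e-10, at most 10^4 power
  iterations; isolated nodes receive teleport-only mass and the mass lost
  on them is redistributed uniformly so scores sum to 1 exactly.
* **Community detection** is multi-level greedy modularity ascent (the
  Louvain procedure). Greedy ascent is sweep-order dependent, so the sweep
  order is drawn under a documented default seed (20140328) and ties in
  the gain break toward the smaller community id: fixed seed in, fixed
  partition out. Reported modularity is always recomputed on the original
  graph by the Newman–Girvan formula.
* **Power-law exponent** is the discrete maximum-likelihood estimate of
  the tail exponent (normalizing constant computed as a generalized zeta
  sum with an Euler–Maclaurin tail correction), with the threshold chosen
  by Kolmogorov–Smirnov minimization when `xmin = "auto"`. A log-log CCDF
  regression slope is reported as a *diagnostic only*: regression on a
  CCDF is the historically common but biased estimator. Fewer than 50
  tail observations, or a degenerate constant sample, produce an explicit
  failed-fit object rather than a number.

## Spectral clustering

`spectral_cluster()` embeds the nodes of (normally) the largest connected
component in the leading eigenvectors of the graph Laplacian `L = D - A`
and partitions the embedding with k-means (10 restarts, seeded). Choices:

* **Unnormalized Laplacian by default**, the symmetric normalized variant
  by flag; row-normalization of the embedding defaults on only for the
  normalized variant, the usual pairing.
* For a connected graph and unnormalized L the constant eigenvector is
  skipped, so k clusters use eigenvectors 2..k.
* **k selection** (`k = "auto"`) uses the eigengap heuristic with
  `k_max = 25`: the number of clusters is the index of the largest
  successive eigenvalue gap. On a disconnected input the zero-eigenvalue
  multiplicity (= component count) is used instead. When the relative
  eigengap at the chosen k is below 0.05 the result is flagged
  `no_structure`: on such graphs (e.g. complete graphs) any balanced
  split is as good as any other and the labels should not be interpreted.

Zero-eigenvalue multiplicity equal to the number of connected components is
exercised as an invariant on random disconnected graphs in the test suite.

## The synthetic corpus generator

No public dataset accompanies the analysis this package operationalizes,
so the generator in `corpus_config()` / `generate_corpus()` *is* the
package's test bed. Its defaults encode the study regime the package
targets — a 1996–2012 corpus of 278 HIV/HPV co-infection studies with
roughly 1,200–1,350 distinct authors:

* **Collaboration sizes**: the author-count distribution over 1..15 is the
  observed one (mean 8.3 authors/paper; the pooled "15 or more" class is
  generated as exactly 15, which keeps the configured mean closed-form).
* **Internationality**: each record is international with probability
  98/278; international records split high–middle / high–low / high–high /
  low–low as 49 : 36 : 11 : 2, with 2–7 affiliation countries.
* **Enrollment counts**: log-normal per pairing class (sdlog 0.4), with
  log-scale locations placing the arithmetic means at the observed
  628 / 637 / 186 / 216 (mixed-extreme pairings enroll ~3x more than
  same-extreme ones) and 280 for domestic studies, which the source
  analysis does not summarize; 5% of counts are missing to exercise the
  explicit-denominator handling downstream.
* **Community structure** is induced at the author-sampling level, not
  post-hoc on the graph, so corpus and graph stay consistent: 8 "core"
  research communities of 125 potential authors each; a core paper draws
  its authors from its home community, each author escaping to a random
  other community with probability 0.10 (these escapes are what bridge the
  communities into one giant component). With probability 0.15 a paper is
  *peripheral*: written by an entirely fresh author group, yielding the
  many small isolated components observed in real collaboration networks.
  0.15 makes the expected peripheral author share ≈ 29%, the observed
  fraction of authors outside the giant component; across seeds the
  default regime gives giant-component shares of ~0.63–0.75 and ~40–60
  components.

What the generator does **not** emulate: temporal growth of the network,
institution-level structure, realistic author-name distributions (so the
normalization/disambiguation code is exercised only on synthetic name
patterns), preferential attachment (the author-degree tail comes from
community reuse, not an explicit power law — heavy-tail recovery is tested
against `sample_power_law_degrees()`, an exact inverse-CDF sampler,
instead), and any correlation between income group and community
membership beyond what the pairing propensities induce. Passing tests on
this generator therefore demonstrate correctness of the *computations*
and the qualitative regime, not fidelity to any real corpus.

`reference_corpus()` is different in kind: a deterministic 278-record
corpus constructed so its marginal tables — collaboration-size columns,
the 49/36/11/2 pairing frequencies over 98 international records, and the
per-pairing mean enrollment counts — equal the published summary tables
exactly. The printed author-count and country-count columns are not
jointly realizable record-by-record together with the per-pairing mean
country counts (the implied totals differ after rounding), so the
reference corpus matches the size columns and the pairing
frequencies/means exactly and lets the per-pairing author/country means
fall where the construction puts them. It exists for exact table
arithmetic, not for network structure: author identities are unique per
record.

## Numerical choices and degenerate inputs

* Percentages and reported means round **half-up** to one decimal
  (`round_half_up()`), the convention of the printed tables, not base R's
  round-half-to-even. Raw (unrounded) values are used in all internal
  computation and JSON serialization.
* All-pairs distances are computed by boolean frontier expansion on a
  dense adjacency matrix — O(diameter) matrix products, appropriate for
  the few-thousand-node graphs this package targets; betweenness is
  Brandes' accumulation; components are BFS.
* The power-iteration PageRank errors out (with iteration diagnostics)
  rather than returning an unconverged vector.
* Edgeless graphs: density of a < 2 node graph, distances, modularity and
  community detection are explicit errors; clustering returns 0s;
  `fit_power_law` returns a failed-fit object on degenerate samples.
* Author identity is exact match on the normalized key (lower-cased,
  whitespace-collapsed, Latin diacritics folded). This is reproducible and
  conservative; homonymous authors merge and spelling variants split, a
  known limitation of any name-keyed disambiguation, so absolute author
  counts are estimates.
* The income table ships as an editable CSV
  (`system.file("extdata", "income_table.csv", package = "coauthnet")`),
  a study-era style three-level classification; classification vintage
  changes group assignments for a handful of countries, which is why the
  table is data, not code, and unmapped countries are always an explicit
  `"unknown"`.
* Seeds: every stochastic operation (corpus generation, SBM sampling,
  community sweep order, k-means restarts, random-graph baselines) takes
  an explicit seed, defaults are documented, and generators restore the
  caller's RNG state — runs are pure functions of (inputs, seed).

## Problem sizes in the test suite

The suite cross-checks every statistic against brute-force enumeration
oracles (Floyd–Warshall, matrix-power path counting, triple enumeration,
union-find, dense linear solves) on the complete atlas of graphs with up
to 7 vertices, and against igraph on hundreds of random graphs of up to 50
nodes; parameter recovery uses 10^5 power-law draws and 90-node planted
block models; end-to-end pipeline tests run 25–60 paper corpora. These
sizes keep the full suite in the minutes range while leaving every code
path exercised; the same functions run unchanged on the full 278-paper
default regime (used in the acceptance script).

## Limitations

Beyond the generator caveats above: the pipeline starts from structured
records (it does not parse PubMed/RIS exports or geocode affiliation
strings); institutions are not modelled, so collaboration-size tables
report author and country columns only; metrics are unweighted by design;
and Laplacian spectral clustering is offered with both Laplacian variants
precisely because the choice is consequential and, for the motivating
analysis, underdetermined.
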