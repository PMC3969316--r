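# Tabular corpus analyses: collaboration-size distributions, income-extreme
# pairing summaries, the small-world assessment against random-graph
# baselines, and the aggregated whole-network statistics report.

PAIRING_LEVELS <- c("high-high", "high-middle", "high-low",
                    "middle-middle", "middle-low", "low-low")

#' Collaboration-size distribution table
#'
#' For each record, the collaboration size is the number of distinct
#' authors (respectively distinct affiliation countries); sizes of 15 and
#' above are pooled into a `"15+"` class. Percentages are rounded half-up
#' to one decimal. Records whose affiliation countries are all unknown are
#' excluded from the country column; their count is in the attribute
#' `n_no_country`.
#'
#' @param corpus a `bib_corpus`.
#' @return data frame (class `collab_size_table`) with columns `size`,
#'   `authors_pct`, `authors_n`, `countries_pct`, `countries_n`; attributes
#'   `n_records` and `n_no_country`.
#' @export
collaboration_size_table <- function(corpus) {
  stopifnot(inherits(corpus, "bib_corpus"))
  sizes <- c(as.character(1:14), "15+")
  bin <- function(counts) {
    pooled <- pmin(counts, 15L)
    tabulate(pooled, nbins = 15L)
  }
  n_auth <- vapply(corpus, function(r) length(r$authors), integer(1))
  cc <- lapply(corpus, record_countries)
  has_country <- vapply(cc, length, integer(1)) > 0
  n_ctry <- vapply(cc[has_country], length, integer(1))
  a_n <- if (length(n_auth)) bin(n_auth) else integer(15)
  c_n <- if (length(n_ctry)) bin(n_ctry) else integer(15)
  pct <- function(x) if (sum(x) == 0) rep(0, 15) else
    round_half_up(100 * x / sum(x), 1)
  out <- data.frame(size = sizes,
                    authors_pct = pct(a_n), authors_n = a_n,
                    countries_pct = pct(c_n), countries_n = c_n,
                    stringsAsFactors = FALSE)
  structure(out, class = c("collab_size_table", "data.frame"),
            n_records = length(corpus), n_no_country = sum(!has_country))
}

#' Classify a country set by its income extremes
#'
#' An international collaboration is labelled by the highest and lowest
#' income levels present among its countries: a collaboration of one
#' high-income and two middle-income countries is `high-middle`, one
#' spanning low, middle and high is `high-low`, and a same-group set is a
#' within-group label (`high-high`, `middle-middle`, `low-low`). Any
#' country with unknown income routes the record to `"unclassified"`.
#'
#' @param countries character vector of at least 2 distinct country codes.
#' @param income_table an [load_income_table()] table.
#' @return one of `"high-high"`, `"high-middle"`, `"high-low"`,
#'   `"middle-middle"`, `"middle-low"`, `"low-low"`, `"unclassified"`.
#' @export
classify_income_extremes <- function(countries, income_table) {
  countries <- unique(toupper(countries))
  if (length(countries) < 2)
    stopf("classify_income_extremes: need >= 2 distinct countries")
  groups <- classify_country(countries, income_table)
  if (any(groups == "unknown")) return("unclassified")
  lev <- match(groups, INCOME_LEVELS)  # low=1 < middle=2 < high=3
  paste(INCOME_LEVELS[max(lev)], INCOME_LEVELS[min(lev)], sep = "-")
}

#' Income-pairing summary of international collaborations
#'
#' Partitions the corpus's international records (two or more distinct
#' affiliation countries) by income-extreme pairing and reports, per
#' pairing: frequency (with percentage share), mean number of authors,
#' mean number of distinct countries, and mean enrollment count. Missing
#' enrollment counts are excluded from the mean and the denominator
#' actually used is reported (`n_sample_size`). All six logically possible
#' pairings are kept as rows even when empty; records containing a country
#' of unknown income group appear under `unclassified`.
#'
#' @param corpus a `bib_corpus`.
#' @param income_table an [load_income_table()] table.
#' @return data frame (class `income_pairing_table`) with one row per
#'   pairing plus `unclassified`; attributes `n_international`,
#'   `n_indeterminate` (records with no affiliation country at all).
#' @export
income_pairing_table <- function(corpus, income_table) {
  stopifnot(inherits(corpus, "bib_corpus"))
  intl <- vapply(corpus, is_international, logical(1))
  n_indeterminate <- sum(is.na(intl))
  recs <- corpus[!is.na(intl) & intl]
  lab <- vapply(recs, function(r)
    classify_income_extremes(record_countries(r), income_table), character(1))
  rows <- c(PAIRING_LEVELS, "unclassified")
  agg <- lapply(rows, function(p) {
    sel <- recs[lab == p]
    ss <- vapply(sel, `[[`, integer(1), "sample_size")
    data.frame(
      pairing = p,
      frequency = length(sel),
      share_pct = NA_real_,  # filled below
      mean_authors = if (length(sel)) round_half_up(
        mean(vapply(sel, function(r) length(r$authors), integer(1))), 1) else NA_real_,
      mean_countries = if (length(sel)) round_half_up(
        mean(vapply(sel, function(r) length(record_countries(r)), integer(1))), 1) else NA_real_,
      mean_sample_size = if (sum(!is.na(ss))) round_half_up(
        mean(ss[!is.na(ss)]), 1) else NA_real_,
      n_sample_size = sum(!is.na(ss)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  total <- sum(out$frequency)
  out$share_pct <- if (total > 0) round_half_up(100 * out$frequency / total, 1)
    else 0
  structure(out, class = c("income_pairing_table", "data.frame"),
            n_international = total, n_indeterminate = n_indeterminate)
}

# Uniform random graph with n nodes and m edges (edges drawn uniformly
# without replacement among the n(n-1)/2 pairs).
random_gnm <- function(n, m) {
  max_m <- n * (n - 1) / 2
  stopifnot(m <= max_m)
  idx <- sample.int(max_m, m)
  # decode pair index -> (i, j), i < j, column-major over the strict upper
  # triangle: pairs (1,2), (1,3), (2,3), (1,4), ...
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  j <- j + (idx > j * (j - 1) / 2) - (idx <= (j - 1) * (j - 2) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
}

#' Small-world assessment against random baselines
#'
#' Compares the observed global clustering coefficient C and average
#' within-component distance L with their means over `n_random` uniform
#' random graphs of the same node and edge count (the "randomly formed
#' network" null whose degree distribution is Poisson-like). The
#' small-world index is `sigma = (C/C_rand) / (L/L_rand)`; the verdict is
#' "small-world" when `sigma > 1` and `C/C_rand > 2` (a documented
#' heuristic: clustering far above the random expectation at comparable
#' distances).
#'
#' @param graph an igraph whose largest component has at least 10 nodes.
#' @param n_random number of random baselines (>= 2).
#' @param seed RNG seed for the baselines.
#' @return list (class `small_world_report`): `C`, `L`, `C_rand`, `L_rand`,
#'   `C_ratio`, `L_ratio`, `sigma`, `small_world`, `n_random`.
#' @export
small_world_report <- function(graph, n_random = 20L, seed = 20140328) {
  if (n_random < 2) stopf("small_world_report: n_random must be >= 2")
  comp <- graph_components(graph)
  if (max(comp$census) < 10)
    stopf("small_world_report: giant component below 10 nodes")
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  C_obs <- clustering_coefficients(graph)$global_C
  L_obs <- distance_stats(graph)$average_distance
  sims <- with_seed(seed, function() {
    vapply(seq_len(n_random), function(i) {
      gr <- random_gnm(n, m)
      Lr <- if (igraph::ecount(gr) > 0) distance_stats(gr)$average_distance
        else NA_real_
      c(clustering_coefficients(gr)$global_C, Lr)
    }, numeric(2))
  })
  C_rand <- mean(sims[1, ], na.rm = TRUE)
  L_rand <- mean(sims[2, ], na.rm = TRUE)
  C_ratio <- C_obs / C_rand
  L_ratio <- L_obs / L_rand
  sigma <- C_ratio / L_ratio
  structure(list(C = C_obs, L = L_obs, C_rand = C_rand, L_rand = L_rand,
                 C_ratio = C_ratio, L_ratio = L_ratio, sigma = sigma,
                 small_world = is.finite(sigma) && sigma > 1 && C_ratio > 2,
                 n_random = n_random),
            class = "small_world_report")
}

#' @export
print.small_world_report <- function(x, ...) {
  cat(sprintf(
    "<small_world_report: C = %.3f (rand %.3f), L = %.2f (rand %.2f), sigma = %.2f -> %s>\n",
    x$C, x$C_rand, x$L, x$L_rand, x$sigma,
    if (x$small_world) "small-world" else "not small-world"))
  invisible(x)
}

#' Whole-network statistics report
#'
#' One call aggregating the whole-network statistics: node/edge counts,
#' average degree, density, global clustering coefficient, average
#' within-component distance and diameter, component census, modularity of
#' the detected communities, a discrete power-law fit to the degree
#' distribution (when at least 50 positive degrees are available), per-node
#' centrality tables, and a spectral-clustering summary of the largest
#' component.
#'
#' @param graph an igraph.
#' @param include_betweenness,include_pagerank,include_spectral stage
#'   toggles (betweenness is the costly one on large graphs).
#' @param clustering_include_low_degree convention switch passed to
#'   [clustering_coefficients()].
#' @param distance_denominator passed to [distance_stats()].
#' @param damping PageRank damping factor.
#' @param seed seed for community detection and spectral clustering.
#' @param spectral_k `"auto"` or an integer.
#' @return list (class `metrics_report`); see fields above. Serializable
#'   with [report_to_json()].
#' @export
network_statistics_report <- function(graph,
                                      include_betweenness = TRUE,
                                      include_pagerank = TRUE,
                                      include_spectral = TRUE,
                                      clustering_include_low_degree = TRUE,
                                      distance_denominator = "within_components",
                                      damping = 0.85,
                                      seed = 20140328,
                                      spectral_k = "auto") {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  deg <- degree_centrality(graph)
  comp <- graph_components(graph)
  clu <- clustering_coefficients(graph,
    include_low_degree = clustering_include_low_degree)
  dstats <- if (m > 0) distance_stats(graph, denominator = distance_denominator)
    else list(average_distance = NA_real_, diameter = NA_integer_, n_pairs = 0L)
  part <- if (m > 0) detect_communities(graph, seed = seed) else NULL
  pl <- if (sum(deg > 0) >= 50) fit_power_law(deg) else NULL
  nodes <- data.frame(name = node_names(graph), degree = as.integer(deg),
                      clustering = unname(clu$local),
                      component = unname(comp$membership),
                      stringsAsFactors = FALSE)
  if (!is.null(igraph::V(graph)$income_group))
    nodes$income_group <- igraph::V(graph)$income_group
  if (include_betweenness) nodes$betweenness <- unname(betweenness_centrality(graph))
  if (include_pagerank && n > 0)
    nodes$pagerank <- unname(pagerank_centrality(graph, damping = damping))
  if (!is.null(part)) nodes$community <- unname(part$membership)
  spec <- NULL
  if (include_spectral && n >= 2 && max(comp$census) >= 3) {
    giant <- largest_component(graph)
    spec <- spectral_cluster(giant, k = spectral_k, seed = seed)
  }
  structure(list(
    n_nodes = n,
    n_edges = m,
    average_degree = if (n > 0) 2 * m / n else NA_real_,
    density = if (n >= 2) graph_density(graph) else NA_real_,
    global_clustering = clu$global_C,
    average_distance = dstats$average_distance,
    diameter = dstats$diameter,
    n_finite_pairs = dstats$n_pairs,
    component_census = comp$census,
    n_components = length(comp$census),
    giant_share = if (n > 0) max(comp$census) / n else NA_real_,
    modularity = if (!is.null(part)) part$modularity else NA_real_,
    n_communities = if (!is.null(part)) max(part$membership) else NA_integer_,
    powerlaw = if (!is.null(pl) && !pl$failed)
      pl[c("alpha", "xmin", "n_tail", "ks")] else NULL,
    spectral = if (!is.null(spec))
      list(k = spec$k, census = spec$census,
           no_structure = spec$no_structure) else NULL,
    seed = seed,
    nodes = nodes
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metrics_report: %d nodes, %d edges>\n",
    "  average degree %.2f, density %.4f\n",
    "  clustering C = %.3f, average distance L = %s, diameter %s\n",
    "  components: %d (giant %.1f%%), modularity Q = %.3f\n"),
    x$n_nodes, x$n_edges, x$average_degree, x$density, x$global_clustering,
    format(round(x$average_distance, 2)), format(x$diameter),
    x$n_components, 100 * x$giant_share, x$modularity))
  if (!is.null(x$powerlaw))
    cat(sprintf("  degree power law: alpha = %.2f (xmin %d, n_tail %d)\n",
                x$powerlaw$alpha, x$powerlaw$xmin, x$powerlaw$n_tail))
  if (!is.null(x$spectral))
    cat(sprintf("  spectral clusters (giant component): k = %d, census [%s]\n",
                x$spectral$k, paste(x$spectral$census, collapse = ", ")))
  invisible(x)
}
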