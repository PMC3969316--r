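# Construction of author-level and country-level co-authorship graphs and
# income-group mixing matrices from a corpus.
#
# A paper with several authors is treated as a scientific collaboration and
# expanded into a clique among its authors (respectively among its
# affiliation countries); every co-occurrence adds one unit of edge weight.
# Downstream statistics treat the graphs as unweighted simple graphs; the
# integer weights are retained as attributes for export (edge width in
# external visualization).

# Aggregate unordered pairs into a weighted undirected simple igraph.
pairs_to_graph <- function(pair_mat, node_names) {
  if (nrow(pair_mat) > 0) {
    a <- pmin(pair_mat[, 1], pair_mat[, 2])
    b <- pmax(pair_mat[, 1], pair_mat[, 2])
    key <- paste(a, b, sep = "\r")
    w <- tapply(rep(1L, length(key)), key, sum)
    uk <- strsplit(names(w), "\r", fixed = TRUE)
    el <- cbind(vapply(uk, `[`, character(1), 1),
                vapply(uk, `[`, character(1), 2))
  } else {
    el <- matrix(character(0), ncol = 2)
    w <- integer(0)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- as.integer(w)
  missing <- setdiff(node_names, igraph::V(g)$name)
  g <- igraph::add_vertices(g, length(missing), name = missing)
  igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
}

#' Build the author co-authorship network
#'
#' One node per distinct normalized author key; for each record, every
#' unordered pair of its authors gains one unit of edge weight (clique
#' expansion). Single-author records contribute isolated nodes. Each author
#' node carries its affiliation countries (union over records), a modal
#' country, and an income group: the group of the author's modal affiliation
#' country, computed by majority across the author's record appearances;
#' ties go to the highest income level present and are flagged in the vertex
#' attribute `income_tie`.
#'
#' @param corpus a `bib_corpus`.
#' @param income_table an [load_income_table()] table.
#' @return an igraph with vertex attributes `kind` (`"author"`), `country`
#'   (modal), `countries` (`;`-joined set), `income_group`, `income_tie`,
#'   `n_papers`, and edge attribute `weight`.
#' @export
build_author_network <- function(corpus, income_table) {
  stopifnot(inherits(corpus, "bib_corpus"), inherits(income_table, "income_table"))
  pair_rows <- list()
  country_votes <- list()  # author -> character vector of per-record countries
  n_papers <- list()
  for (r in corpus) {
    keys <- vapply(r$authors, `[[`, character(1), "name_key")
    if (length(keys) >= 2) {
      cmb <- utils::combn(sort(unique(keys)), 2)
      pair_rows[[length(pair_rows) + 1L]] <- t(cmb)
    }
    for (a in r$authors) {
      country_votes[[a$name_key]] <- c(country_votes[[a$name_key]], a$countries)
      n_papers[[a$name_key]] <- (n_papers[[a$name_key]] %||% 0L) + 1L
    }
  }
  all_authors <- sort(unique(names(country_votes)))
  pm <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    matrix(character(0), ncol = 2)
  g <- pairs_to_graph(pm, all_authors)
  nm <- igraph::V(g)$name
  modal <- character(length(nm)); tie <- logical(length(nm))
  group <- character(length(nm)); allc <- character(length(nm))
  for (i in seq_along(nm)) {
    votes <- country_votes[[nm[i]]]
    allc[i] <- paste(sort(unique(votes)), collapse = ";")
    if (length(votes) == 0) {
      modal[i] <- NA_character_; group[i] <- "unknown"; tie[i] <- FALSE
    } else {
      tab <- table(votes)
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) > 1) {
        lev <- classify_country(winners, income_table)
        ord <- match(lev, c("unknown", INCOME_LEVELS))  # highest income wins
        winners <- winners[order(-ord, winners)]
        tie[i] <- TRUE
      }
      modal[i] <- winners[1]
      group[i] <- classify_country(modal[i], income_table)
    }
  }
  igraph::V(g)$kind <- "author"
  igraph::V(g)$country <- modal
  igraph::V(g)$countries <- allc
  igraph::V(g)$income_group <- group
  igraph::V(g)$income_tie <- tie
  igraph::V(g)$n_papers <- as.integer(unlist(n_papers[nm]))
  igraph::graph_attr(g, "source_corpus") <- attr(corpus, "source_id")
  igraph::graph_attr(g, "entity") <- "author"
  g
}

#' Build the country collaboration network
#'
#' One node per country appearing in any author affiliation; for each
#' record, every unordered pair of distinct countries in the record's
#' affiliation-country union gains one unit of edge weight. Single-country
#' records contribute nodes without edges. Records with no affiliation
#' country at all are skipped; their count is stored in the graph attribute
#' `n_skipped_no_country`.
#'
#' @inheritParams build_author_network
#' @return an igraph with vertex attributes `kind` (`"country"`), `country`,
#'   `income_group`, and edge attribute `weight`.
#' @export
build_country_network <- function(corpus, income_table) {
  stopifnot(inherits(corpus, "bib_corpus"), inherits(income_table, "income_table"))
  pair_rows <- list()
  seen <- character(0)
  skipped <- 0L
  for (r in corpus) {
    cc <- record_countries(r)
    if (length(cc) == 0) { skipped <- skipped + 1L; next }
    seen <- union(seen, cc)
    if (length(cc) >= 2)
      pair_rows[[length(pair_rows) + 1L]] <- t(utils::combn(cc, 2))
  }
  pm <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    matrix(character(0), ncol = 2)
  g <- pairs_to_graph(pm, sort(seen))
  igraph::V(g)$kind <- "country"
  igraph::V(g)$country <- igraph::V(g)$name
  igraph::V(g)$income_group <- classify_country(igraph::V(g)$name, income_table)
  igraph::graph_attr(g, "source_corpus") <- attr(corpus, "source_id")
  igraph::graph_attr(g, "entity") <- "country"
  igraph::graph_attr(g, "n_skipped_no_country") <- skipped
  g
}

#' Record-level mixing matrix over country groups
#'
#' Cross-tabulates records by the groups their affiliation countries belong
#' to. For two distinct groups g != h, entry (g, h) is the number of records
#' whose country union intersects both; the diagonal (g, g) counts records
#' whose union lies entirely within g. Countries not covered by `grouping`
#' fall into an `"unknown"` group. The matrix is symmetric with non-negative
#' integer entries.
#'
#' @param corpus a `bib_corpus`.
#' @param grouping either an `income_table` (groups = income levels) or a
#'   named character vector mapping country code to group label.
#' @return symmetric integer matrix with group-labelled dimnames.
#' @export
mixing_matrix <- function(corpus, grouping) {
  stopifnot(inherits(corpus, "bib_corpus"))
  lookup <- function(cc) {
    if (inherits(grouping, "income_table")) classify_country(cc, grouping)
    else {
      out <- unname(grouping[cc])
      out[is.na(out)] <- "unknown"
      out
    }
  }
  labels <- sort(unique(c(
    if (inherits(grouping, "income_table")) grouping$group else unname(grouping),
    "unknown")))
  M <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (r in corpus) {
    cc <- record_countries(r)
    if (length(cc) == 0) next
    gs <- unique(lookup(cc))
    if (length(gs) == 1) {
      M[gs, gs] <- M[gs, gs] + 1L
    } else {
      pr <- utils::combn(sort(gs), 2)
      for (j in seq_len(ncol(pr))) {
        M[pr[1, j], pr[2, j]] <- M[pr[1, j], pr[2, j]] + 1L
        M[pr[2, j], pr[1, j]] <- M[pr[2, j], pr[1, j]] + 1L
      }
    }
  }
  M
}

#' Induced subgraph on the largest connected component
#'
#' Component membership is determined by breadth-first traversal; among
#' components of equal (maximal) size the one containing the smallest node
#' label wins, so the result is deterministic.
#'
#' @param graph an igraph.
#' @return the induced subgraph (vertex/edge attributes preserved).
#' @export
largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0) stopf("largest_component: empty graph")
  comp <- graph_components(graph)
  sizes <- tabulate(comp$membership)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # smallest node label decides; vertices are scanned in name order
    nm <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
    first_label <- vapply(best, function(b) min(nm[comp$membership == b]),
                          character(1))
    best <- best[order(first_label)][1]
  } else best <- best[1]
  igraph::induced_subgraph(graph, which(comp$membership == best))
}
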