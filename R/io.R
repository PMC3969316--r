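# Graph/table/report writers, anonymization, and the end-to-end pipeline.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

#' Anonymize node identities
#'
#' Replaces node names by stable pseudonymous ids derived from a salted
#' FNV-1a hash of the name: the same salt always yields the same
#' pseudonyms, different salts decouple runs. All other vertex attributes
#' (country, income group, degree, ...) are preserved, so the anonymized
#' graph has the identical structure and attribute profile; only the
#' side-table returned alongside can reverse the mapping.
#'
#' @param graph an igraph with named vertices.
#' @param salt character salt keyed into the hash.
#' @return list with `graph` (names replaced) and `key` (data frame
#'   `pseudonym`, `name`).
#' @export
anonymize_graph <- function(graph, salt = "coauthnet") {
  nm <- node_names(graph)
  h <- fnv1a32(paste0(salt, "\r", nm))
  pseudo <- paste0("N", h)
  # resolve rare collisions deterministically, in name order
  while (anyDuplicated(pseudo)) {
    dup <- duplicated(pseudo)
    pseudo[dup] <- paste0("N", fnv1a32(paste0(salt, "\r", nm[dup], "\r+")))
  }
  key <- data.frame(pseudonym = pseudo, name = nm, stringsAsFactors = FALSE)
  igraph::V(graph)$name <- pseudo
  list(graph = graph, key = key)
}

#' Write a graph as edge-list TSV
#'
#' Columns `u`, `v`, `weight` (weight 1 when the graph carries none).
#' Isolated nodes do not appear; export GraphML/GEXF for a lossless dump.
#'
#' @param graph an igraph.
#' @param path output path.
#' @export
write_edgelist_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight %||% rep(1L, nrow(el))
  df <- data.frame(u = el[, 1], v = el[, 2], weight = w,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph to GraphML
#'
#' Lossless attribute export (node kind, country, income group, degree,
#' edge weight) via igraph's GraphML writer; a `degree` vertex attribute is
#' added so visualization tools can size nodes without recomputation.
#'
#' @inheritParams write_edgelist_tsv
#' @export
write_graphml <- function(graph, path) {
  igraph::V(graph)$degree <- as.integer(degree_centrality(graph))
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Write a graph to GEXF
#'
#' Minimal GEXF 1.2 writer covering what downstream visualization needs:
#' node labels, node attributes (kind, country, income_group, degree) and
#' edge weights (collaboration counts, rendered as edge width).
#'
#' @inheritParams write_edgelist_tsv
#' @export
write_gexf <- function(graph, path) {
  nm <- node_names(graph)
  n <- igraph::vcount(graph)
  deg <- degree_centrality(graph)
  attrs <- list(kind = igraph::V(graph)$kind,
                country = igraph::V(graph)$country,
                income_group = igraph::V(graph)$income_group)
  attrs <- Filter(Negate(is.null), attrs)
  attr_names <- c(names(attrs), "degree")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(fmt, ...) cat(sprintf(fmt, ...), file = con, sep = "")
  w('<?xml version="1.0" encoding="UTF-8"?>\n')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">\n')
  w('  <graph mode="static" defaultedgetype="undirected">\n')
  w('    <attributes class="node">\n')
  for (ai in seq_along(attr_names)) {
    type <- if (attr_names[ai] == "degree") "integer" else "string"
    w('      <attribute id="%d" title="%s" type="%s"/>\n', ai - 1L,
      attr_names[ai], type)
  }
  w('    </attributes>\n    <nodes>\n')
  for (i in seq_len(n)) {
    w('      <node id="%s" label="%s">\n        <attvalues>\n',
      xml_escape(nm[i]), xml_escape(nm[i]))
    for (ai in seq_along(attrs)) {
      val <- attrs[[ai]][i]
      if (!is.na(val))
        w('          <attvalue for="%d" value="%s"/>\n', ai - 1L,
          xml_escape(as.character(val)))
    }
    w('          <attvalue for="%d" value="%d"/>\n', length(attrs), deg[i])
    w('        </attvalues>\n      </node>\n')
  }
  w('    </nodes>\n    <edges>\n')
  el <- igraph::as_edgelist(graph)
  ew <- igraph::E(graph)$weight %||% rep(1L, nrow(el))
  for (e in seq_len(nrow(el))) {
    w('      <edge id="%d" source="%s" target="%s" weight="%s"/>\n',
      e - 1L, xml_escape(el[e, 1]), xml_escape(el[e, 2]), format(ew[e]))
  }
  w('    </edges>\n  </graph>\n</gexf>\n')
  invisible(path)
}

#' Write a data frame as TSV
#' @param df data frame.
#' @param path output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a data frame as a Markdown table
#' @inheritParams write_table_tsv
#' @export
write_table_markdown <- function(df, path) {
  cells <- as.data.frame(lapply(df, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- ""
    out
  }), stringsAsFactors = FALSE)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  writeLines(c(header, sep, body), path)
  invisible(path)
}

# Strip the per-node table for JSON serialization; numbers are emitted
# unrounded so reruns are byte-identical.
#' Serialize a metrics report (or any report list) to JSON
#'
#' @param report a `metrics_report` or similar list.
#' @param path output path.
#' @param include_nodes include the per-node table.
#' @export
report_to_json <- function(report, path, include_nodes = FALSE) {
  obj <- unclass(report)
  if (!include_nodes) obj$nodes <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Either simulate a corpus (`simulate = TRUE`, using [corpus_config()]
#' parameters via `corpus`) or read one from `corpus_path`
#' (CSV or JSON by extension). All seeds are recorded in the outputs.
#'
#' @param output_dir directory for the artifact bundle (created).
#' @param corpus_path path to a corpus CSV/JSON, or `NULL` to simulate.
#' @param income_table_path path to an income CSV, or `NULL` for the
#'   packaged table.
#' @param seed master seed (used for simulation and all seeded stages).
#' @param corpus optional [corpus_config()] overriding the simulated corpus.
#' @param include_betweenness,spectral_k,damping,clustering_include_low_degree,distance_denominator
#'   metric options, see [network_statistics_report()].
#' @param n_random small-world baseline count.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            corpus_path = NULL,
                            income_table_path = NULL,
                            seed = 20140328,
                            corpus = NULL,
                            include_betweenness = TRUE,
                            spectral_k = "auto",
                            damping = 0.85,
                            clustering_include_low_degree = TRUE,
                            distance_denominator = "within_components",
                            n_random = 20L) {
  if (!is.null(corpus_path) && !file.exists(corpus_path))
    stopf("pipeline_config: corpus_path '%s' does not exist", corpus_path)
  if (!is.null(income_table_path) && !file.exists(income_table_path))
    stopf("pipeline_config: income_table_path '%s' does not exist",
          income_table_path)
  structure(list(output_dir = output_dir, corpus_path = corpus_path,
                 income_table_path = income_table_path, seed = as.integer(seed),
                 corpus = corpus,
                 include_betweenness = include_betweenness,
                 spectral_k = spectral_k, damping = damping,
                 clustering_include_low_degree = clustering_include_low_degree,
                 distance_denominator = distance_denominator,
                 n_random = as.integer(n_random)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipeline_config()] arguments.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$corpus) && !inherits(obj$corpus, "corpus_config")) {
    if (is.null(obj$corpus$seed)) obj$corpus$seed <- obj$seed %||% 20140328
    obj$corpus <- do.call(corpus_config, obj$corpus)
  }
  do.call(pipeline_config, obj)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  flat <- paste(deparse(cfg[sort(names(cfg))]), collapse = "")
  fnv1a32(flat)
}

#' Run the full analysis pipeline
#'
#' Executes the four stages — corpus (load or simulate), network
#' construction (author and country networks, mixing matrix), metrics
#' (whole-network statistics report with spectral clustering), summaries
#' (collaboration-size table, income-pairing table, small-world report) —
#' and writes the artifact bundle into `config$output_dir`: graphs as
#' GraphML/GEXF/TSV, tables as TSV and Markdown, reports as JSON, plus a
#' run manifest (`manifest.json`) listing package version, config hash,
#' seeds and completed stages. Outputs are deterministic: re-running with
#' the same config yields byte-identical files.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  income <- load_income_table(config$income_table_path)
  stages <- character(0)

  # stage 1: corpus
  if (!is.null(config$corpus_path)) {
    corpus <- if (grepl("\\.json$", config$corpus_path, ignore.case = TRUE))
      read_corpus_json(config$corpus_path) else read_corpus_csv(config$corpus_path)
  } else {
    cc <- config$corpus %||% corpus_config(seed = config$seed)
    corpus <- generate_corpus(cc)
    write_corpus_csv(corpus, file.path(out, "corpus.csv"))
    jsonlite::write_json(
      list(seed = cc$seed, n_papers = cc$n_papers,
           config_hash = config_hash(cc)),
      file.path(out, "corpus_provenance.json"), auto_unbox = TRUE)
  }
  stages <- c(stages, "corpus")

  # stage 2: networks
  g_auth <- build_author_network(corpus, income)
  g_ctry <- build_country_network(corpus, income)
  mm <- mixing_matrix(corpus, income)
  write_graphml(g_auth, file.path(out, "author_network.graphml"))
  write_gexf(g_auth, file.path(out, "author_network.gexf"))
  write_edgelist_tsv(g_auth, file.path(out, "author_network.tsv"))
  write_graphml(g_ctry, file.path(out, "country_network.graphml"))
  write_gexf(g_ctry, file.path(out, "country_network.gexf"))
  write_edgelist_tsv(g_ctry, file.path(out, "country_network.tsv"))
  write_table_tsv(as.data.frame(as.table(mm), responseName = "records") |>
                    stats::setNames(c("group_1", "group_2", "records")),
                  file.path(out, "mixing_matrix.tsv"))
  stages <- c(stages, "networks")

  # stage 3: metrics (+ spectral on the giant component)
  report <- network_statistics_report(
    g_auth,
    include_betweenness = config$include_betweenness,
    clustering_include_low_degree = config$clustering_include_low_degree,
    distance_denominator = config$distance_denominator,
    damping = config$damping, seed = config$seed,
    spectral_k = config$spectral_k)
  report_to_json(report, file.path(out, "metrics_report.json"))
  write_table_tsv(report$nodes, file.path(out, "author_metrics.tsv"))
  stages <- c(stages, "metrics")

  # stage 4: summaries
  cst <- collaboration_size_table(corpus)
  ipt <- income_pairing_table(corpus, income)
  write_table_tsv(cst, file.path(out, "collaboration_size_table.tsv"))
  write_table_markdown(cst, file.path(out, "collaboration_size_table.md"))
  write_table_tsv(ipt, file.path(out, "income_pairing_table.tsv"))
  write_table_markdown(ipt, file.path(out, "income_pairing_table.md"))
  sw <- small_world_report(g_auth, n_random = config$n_random,
                           seed = config$seed)
  report_to_json(sw, file.path(out, "small_world_report.json"))
  stages <- c(stages, "summaries")

  manifest <- list(
    package = "coauthnet",
    version = as.character(utils::packageVersion("coauthnet")),
    config_hash = config_hash(config),
    seed = config$seed,
    n_records = length(corpus),
    stages = stages,
    files = sort(setdiff(list.files(out), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
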