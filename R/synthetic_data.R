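# Synthetic bibliographic corpora and benchmark graphs.
#
# The generator emulates the regime of a 1996-2012 corpus of HIV/HPV
# co-infection epidemiology: ~278 papers and ~1,300 distinct authors, about
# 65% single-country studies, international collaborations dominated by
# high-middle and high-low income pairings whose enrollment counts run
# roughly three times larger than same-extreme collaborations, and a
# co-authorship graph with one giant component around 70% of authors plus
# dozens of small isolated components.

SIZE_COUNTS <- c(0, 2, 10, 13, 21, 40, 39, 23, 30, 34, 26, 16, 7, 5, 12)
INTL_COUNTRY_COUNTS <- c(66, 18, 7, 5, 1, 1)  # records with 2..7 countries
PAIRING_COUNTS <- c(high_middle = 49, high_low = 36, high_high = 11,
                    low_low = 2)
PAIRING_MEAN_SS <- c(high_middle = 628, high_low = 637, high_high = 186,
                     low_low = 216)

POOL_HIGH <- c("USA", "GBR", "FRA", "NLD", "SWE", "NOR", "FIN", "CAN",
               "DEU", "ITA")
POOL_MIDDLE <- c("BRA", "ZAF", "MEX", "THA", "CHL", "ARG", "COL")
POOL_LOW <- c("UGA", "KEN", "TZA", "MWI", "SEN", "RWA", "COD")

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the study regime the package targets: 278 papers; a
#' collaboration-size distribution over 1..15 authors peaking at 6-10 authors
#' per paper (mean 8.3); 98/278 international records split
#' high-middle/high-low/high-high/low-low in proportions 49:36:11:2;
#' log-normal enrollment counts whose means follow the observed gradient
#' (mixed-extreme pairings around 630 participants, same-extreme around
#' 190-220, domestic 280); and community structure induced at the
#' author-sampling level: a "core" of `n_blocks` research communities whose
#' papers occasionally recruit across blocks (giving one giant component),
#' plus a fraction `p_peripheral` of papers written by entirely fresh author
#' groups (giving many small isolated components).
#'
#' @param seed integer RNG seed (mandatory; every generator run is a pure
#'   function of its config including the seed).
#' @param n_papers number of records to generate.
#' @param size_probs probability over author counts 1..15 (15 = the pooled
#'   "15 or more" class, generated as exactly 15).
#' @param p_international probability a record involves several countries.
#' @param pairing_probs probability over income pairings for international
#'   records (names `high_middle`, `high_low`, `high_high`, `low_low`).
#' @param intl_country_count_probs probability over 2..7 affiliation
#'   countries for an international record (capped at the author count).
#' @param n_blocks,block_size core research communities and authors per
#'   community.
#' @param p_offblock probability an author of a core paper is recruited from
#'   a random other block (bridges between communities).
#' @param p_peripheral probability a paper is written by a fresh, isolated
#'   author group.
#' @param domestic_income_probs income-level distribution of single-country
#'   records (names `high`, `middle`, `low`).
#' @param sample_size_meanlog named log-scale locations of the log-normal
#'   enrollment-count model per pairing class (plus `domestic`); defaults
#'   place the arithmetic means at 628/637/186/216/280.
#' @param sample_size_sdlog log-scale spread of the enrollment-count model.
#' @param sample_size_missing probability the enrollment count is missing.
#' @param country_pools list of ISO alpha-3 pools (`high`, `middle`, `low`).
#' @return a validated `corpus_config` list.
#' @export
corpus_config <- function(seed,
                          n_papers = 278L,
                          size_probs = SIZE_COUNTS / sum(SIZE_COUNTS),
                          p_international = 98 / 278,
                          pairing_probs = PAIRING_COUNTS / sum(PAIRING_COUNTS),
                          intl_country_count_probs =
                            INTL_COUNTRY_COUNTS / sum(INTL_COUNTRY_COUNTS),
                          n_blocks = 8L,
                          block_size = 125L,
                          p_offblock = 0.10,
                          p_peripheral = 0.15,
                          domestic_income_probs =
                            c(high = 0.60, middle = 0.25, low = 0.15),
                          sample_size_meanlog =
                            log(c(PAIRING_MEAN_SS, domestic = 280)) - 0.4^2 / 2,
                          sample_size_sdlog = 0.4,
                          sample_size_missing = 0.05,
                          country_pools = list(high = POOL_HIGH,
                                               middle = POOL_MIDDLE,
                                               low = POOL_LOW)) {
  if (missing(seed) || !is_count(seed)) stopf("corpus_config: seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_papers = as.integer(n_papers),
              size_probs = size_probs, p_international = p_international,
              pairing_probs = pairing_probs,
              intl_country_count_probs = intl_country_count_probs,
              n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size),
              p_offblock = p_offblock, p_peripheral = p_peripheral,
              domestic_income_probs = domestic_income_probs,
              sample_size_meanlog = sample_size_meanlog,
              sample_size_sdlog = sample_size_sdlog,
              sample_size_missing = sample_size_missing,
              country_pools = country_pools)
  for (p in list(cfg$size_probs, cfg$pairing_probs,
                 cfg$intl_country_count_probs, cfg$domestic_income_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stopf("corpus_config: probabilities must be non-negative and sum to 1")
  }
  if (cfg$n_papers < 0) stopf("corpus_config: n_papers must be >= 0")
  if (cfg$n_blocks < 1 || cfg$block_size < 1)
    stopf("corpus_config: block sizes must be >= 1")
  stopifnot(length(cfg$size_probs) == 15,
            length(cfg$intl_country_count_probs) == 6,
            setequal(names(cfg$pairing_probs), names(PAIRING_COUNTS)))
  class(cfg) <- "corpus_config"
  cfg
}

# Run fn with the RNG seeded, restoring the caller's RNG state afterwards so
# generators are pure functions of (config, seed).
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

JOURNAL_POOL <- c("J Infect Dis", "AIDS", "Int J Cancer", "Lancet",
                  "Sex Transm Dis", "J Acquir Immune Defic Syndr",
                  "Gynecol Oncol", "Br J Cancer")

#' Generate a synthetic bibliographic corpus
#'
#' Reproducible under a fixed seed: each record draws an author count from
#' the configured size distribution, a home research community, authors
#' preferentially within that community (or a fresh isolated author group
#' with probability `p_peripheral`), an income pairing and country set, and
#' a pairing-conditional log-normal enrollment count.
#'
#' @param config a [corpus_config()].
#' @return a `bib_corpus` of `config$n_papers` records.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  with_seed(config$seed, function() {
    pools <- config$country_pools
    records <- vector("list", config$n_papers)
    for (i in seq_len(config$n_papers)) {
      s <- sample.int(15L, 1L, prob = config$size_probs)
      if (s > config$n_blocks * config$block_size)
        stopf("generate_corpus: author pool (%d) smaller than collaboration size %d",
              config$n_blocks * config$block_size, s)
      intl <- stats::runif(1) < config$p_international
      if (intl && s >= 2) {
        pairing <- sample(names(config$pairing_probs), 1L,
                          prob = config$pairing_probs)
        nc <- min(sample(2:7, 1L, prob = config$intl_country_count_probs), s)
        cs <- switch(pairing,
          high_middle = c(sample(pools$high, 1L),
                          sample(pools$middle, nc - 1L)),
          high_low = c(sample(pools$high, 1L), sample(pools$low, nc - 1L)),
          high_high = sample(pools$high, nc),
          low_low = sample(pools$low, nc))
        class_lab <- pairing
      } else {
        lev <- sample(names(config$domestic_income_probs), 1L,
                      prob = config$domestic_income_probs)
        cs <- sample(pools[[lev]], 1L)
        class_lab <- "domestic"
      }
      nc <- length(cs)
      peripheral <- stats::runif(1) < config$p_peripheral
      if (peripheral) {
        names_raw <- sprintf("Peri%04d, A%02d", i, seq_len(s))
      } else {
        home <- sample.int(config$n_blocks, 1L)
        blocks <- ifelse(stats::runif(s) < config$p_offblock,
                         sample.int(config$n_blocks, s, replace = TRUE), home)
        idx <- sample.int(config$block_size, s, replace = TRUE)
        names_raw <- sprintf("Core%02d, A%03d", blocks, idx)
        dup <- duplicated(names_raw)
        guard <- 0L
        while (any(dup)) {  # re-draw clashes so a record never repeats an author
          idx[dup] <- sample.int(config$block_size, sum(dup), replace = TRUE)
          names_raw <- sprintf("Core%02d, A%03d", blocks, idx)
          dup <- duplicated(names_raw)
          guard <- guard + 1L
          if (guard > 1000L) stopf("generate_corpus: cannot draw %d distinct authors", s)
        }
      }
      authors <- lapply(seq_len(s), function(j)
        author_ref(names_raw[j], cs[((j - 1L) %% nc) + 1L]))
      ss <- if (stats::runif(1) < config$sample_size_missing) NA_integer_ else
        max(1L, as.integer(round(stats::rlnorm(
          1, config$sample_size_meanlog[[class_lab]],
          config$sample_size_sdlog))))
      records[[i]] <- bib_record(
        record_id = sprintf("syn%04d", i),
        year = sample(1996:2012, 1L),
        title = sprintf("Synthetic co-infection study %04d", i),
        journal = sample(JOURNAL_POOL, 1L),
        sample_size = ss,
        enrollment_countries = cs,
        authors = authors)
    }
    bib_corpus(records, source_id = sprintf("synthetic(seed=%d)", config$seed))
  })
}

#' Deterministic reference corpus reproducing the published marginal tables
#'
#' A corpus of 278 records built by direct construction (no randomness) so
#' that its collaboration-size columns (authors and affiliation countries),
#' its income-pairing frequencies (49/36/11/2 over 98 international
#' records) and its per-pairing mean enrollment counts (628/637/186/216)
#' equal the printed summary tables of the HIV/HPV collaboration study
#' regime this package emulates. Author identities are synthetic and unique
#' per record: this corpus exists for exact table arithmetic, not for
#' network structure.
#'
#' @return a `bib_corpus` of 278 records.
#' @export
reference_corpus <- function() {
  author_counts <- rep(15:1, rev(SIZE_COUNTS))      # descending
  country_counts <- c(rep(7:2, rev(INTL_COUNTRY_COUNTS)),
                      rep(1L, 180L))                # descending; len 278
  stopifnot(length(author_counts) == 278, length(country_counts) == 278)
  pairing_seq <- rep(names(PAIRING_COUNTS), PAIRING_COUNTS)
  domestic_levels <- rep(c("high", "high", "middle", "high", "low"),
                         length.out = 180)
  pools <- list(high = POOL_HIGH, middle = POOL_MIDDLE, low = POOL_LOW)
  records <- vector("list", 278L)
  intl_i <- 0L
  dom_i <- 0L
  for (i in 1:278) {
    s <- author_counts[i]
    nc <- country_counts[i]
    stopifnot(s >= nc)
    if (nc >= 2) {
      intl_i <- intl_i + 1L
      pairing <- pairing_seq[intl_i]
      cs <- switch(pairing,
        high_middle = c(pools$high[1L + intl_i %% 3],
                        pools$middle[seq_len(nc - 1L)]),
        high_low = c(pools$high[1L + intl_i %% 3],
                     pools$low[seq_len(nc - 1L)]),
        high_high = pools$high[seq_len(nc)],
        low_low = pools$low[seq_len(nc)])
      ss <- PAIRING_MEAN_SS[[pairing]]
    } else {
      dom_i <- dom_i + 1L
      lev <- domestic_levels[dom_i]
      cs <- pools[[lev]][1L + dom_i %% length(pools[[lev]])]
      ss <- 150L
    }
    authors <- lapply(seq_len(s), function(j)
      author_ref(sprintf("Ref%04d, A%02d", i, j), cs[((j - 1L) %% nc) + 1L]))
    records[[i]] <- bib_record(
      record_id = sprintf("ref%04d", i),
      year = 1996L + (i %% 17L),
      title = sprintf("Reference study %04d", i),
      journal = JOURNAL_POOL[1L + i %% length(JOURNAL_POOL)],
      sample_size = as.integer(ss),
      enrollment_countries = cs,
      authors = authors)
  }
  bib_corpus(records, source_id = "reference")
}

#' Sample a stochastic block model graph
#'
#' Undirected simple graph with planted groups: node pairs within a block
#' are joined independently with probability `p_in`, pairs across blocks
#' with `p_out`. Ground-truth block labels are stored in the vertex
#' attribute `block`; the graph attribute `planted` records whether
#' `p_in > p_out` (when equal there is no planted structure to recover).
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out within/between-block edge probabilities,
#'   `0 <= p_out <= p_in <= 1`.
#' @param seed RNG seed.
#' @return an igraph with vertex attribute `block`.
#' @export
generate_sbm_graph <- function(block_sizes, p_in, p_out, seed) {
  if (!is.numeric(p_in) || !is.numeric(p_out) || p_in < 0 || p_in > 1 ||
      p_out < 0 || p_out > 1 || p_out > p_in)
    stopf("generate_sbm_graph: need 0 <= p_out <= p_in <= 1")
  if (!is_count(seed)) stopf("generate_sbm_graph: seed is mandatory")
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  with_seed(seed, function() {
    pr <- utils::combn(n, 2)
    same <- labels[pr[1, ]] == labels[pr[2, ]]
    p <- ifelse(same, p_in, p_out)
    keep <- stats::runif(ncol(pr)) < p
    g <- igraph::graph_from_edgelist(t(pr[, keep, drop = FALSE]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
    igraph::V(g)$block <- labels
    igraph::graph_attr(g, "planted") <- p_in > p_out
    g
  })
}

#' Draw from a discrete power-law distribution
#'
#' I.i.d. draws from `P(X = k) \eqn{\propto} k^(-alpha)` for `k >= xmin`,
#' via the inverse CDF on a precomputed table. The support is truncated at
#' `cap` (default `1e6`); for `alpha` well above 1 the truncated tail mass
#' is negligible (for `alpha = 2.5`, `xmin = 1` it is below `1e-9`).
#'
#' @param alpha exponent, must exceed 1 (the distribution is not
#'   normalizable otherwise).
#' @param xmin smallest attainable value (integer >= 1).
#' @param n number of draws.
#' @param seed RNG seed.
#' @param cap truncation point of the support.
#' @return integer vector of length `n`, all `>= xmin`.
#' @export
sample_power_law_degrees <- function(alpha, xmin = 1L, n, seed, cap = 1e6) {
  if (!is.numeric(alpha) || alpha <= 1)
    stopf("sample_power_law_degrees: alpha must be > 1")
  if (!is_count(xmin) || xmin < 1) stopf("xmin must be an integer >= 1")
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  if (!is_count(seed)) stopf("seed is mandatory")
  k <- seq.int(xmin, cap)
  w <- k^(-alpha)
  cdf <- cumsum(w) / sum(w)
  with_seed(seed, function() {
    u <- stats::runif(n)
    as.integer(k[findInterval(u, cdf) + 1L])
  })
}
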