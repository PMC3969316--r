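# Small corpora and income tables built in code for the unit tests.

test_income_table <- function() {
  path <- tempfile(fileext = ".csv")
  writeLines(c("country_code,group",
               "USA,high", "GBR,high", "FRA,high", "NLD,high",
               "BRA,middle", "ZAF,middle", "MEX,middle", "THA,middle",
               "UGA,low", "KEN,low", "TZA,low", "MWI,low"), path)
  load_income_table(path)
}

# record with authors given as "Name" = country vector
make_record <- function(id, authors, sample_size = NA, year = 2005) {
  bib_record(record_id = id,
             year = year,
             title = paste("study", id),
             journal = "J Test",
             sample_size = sample_size,
             enrollment_countries = unique(unlist(authors)),
             authors = lapply(names(authors), function(nm)
               author_ref(nm, authors[[nm]])))
}

# five mixed records with a hand-enumerable group structure
mixed_fixture_corpus <- function() {
  bib_corpus(list(
    make_record("r1", list("Smith, A" = "USA", "Jones, B" = "USA"),
                sample_size = 100),
    make_record("r2", list("Smith, A" = "USA", "Okello, C" = "UGA",
                           "Mbeki, D" = "ZAF"), sample_size = 400),
    make_record("r3", list("Silva, E" = "BRA", "Costa, F" = "BRA"),
                sample_size = 50),
    make_record("r4", list("Okello, C" = "UGA", "Wanjiru, G" = "KEN"),
                sample_size = 250),
    make_record("r5", list("Smith, A" = c("USA", "GBR"), "Silva, E" = "BRA"))
  ), source_id = "mixed-fixture")
}

# brute-force pairwise co-occurrence counts of authors across records
oracle_cooccurrence <- function(corpus) {
  keys <- sort(unique(unlist(lapply(corpus, function(r)
    vapply(r$authors, `[[`, character(1), "name_key")))))
  W <- matrix(0L, length(keys), length(keys), dimnames = list(keys, keys))
  for (r in corpus) {
    ks <- unique(vapply(r$authors, `[[`, character(1), "name_key"))
    for (a in ks) for (b in ks) if (a < b) {
      W[a, b] <- W[a, b] + 1L
      W[b, a] <- W[b, a] + 1L
    }
  }
  W
}

# random small corpus for property tests
random_corpus <- function(n_records, n_authors = 12, seed) {
  pool <- sprintf("Author, %s", LETTERS[seq_len(n_authors)])
  countries <- c("USA", "GBR", "BRA", "UGA", "KEN")
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n_records), function(i) {
      k <- sample(1:5, 1)
      nm <- sample(pool, k)
      auth <- lapply(nm, function(x)
        author_ref(x, sample(countries, sample(0:2, 1))))
      bib_record(sprintf("r%03d", i), authors = auth,
                 year = sample(1996:2012, 1),
                 sample_size = if (runif(1) < 0.2) NA else sample(20:900, 1))
    })
    bib_corpus(recs, source_id = sprintf("random-%d", seed))
  })
}
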