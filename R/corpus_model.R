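# Data model for bibliographic records, author identities and income-group
# classification.
#
# A corpus is a list of records; each record carries the fields extracted
# from a publication: year, title, journal, number of participants enrolled,
# enrollment countries, and the ordered author list with per-author
# affiliation countries. Country codes are ISO 3166-1 alpha-3. Income groups
# follow the World Bank three-level scheme (low / middle / high), with the
# two middle sub-levels collapsed.

INCOME_LEVELS <- c("low", "middle", "high")

#' Normalize an author name into a stable identity key
#'
#' Author identity across records is resolved by exact match on a normalized
#' key: lower-cased, whitespace-collapsed, diacritics stripped. This is
#' deliberately conservative and reproducible; its known failure modes
#' (homonyms merge, spelling variants split) are discussed in the vignette.
#'
#' @param raw_name character vector of author names as extracted.
#' @return character vector of normalized keys.
#' @examples
#' normalize_author("Palefsky, J")      # "palefsky, j"
#' normalize_author(" Shah,  KV ")      # "shah, kv"
#' normalize_author("Gonçalves, M") # "goncalves, m"
#' @export
normalize_author <- function(raw_name) {
  if (length(raw_name) == 0) stopf("normalize_author: empty input")
  if (!is.character(raw_name)) stopf("normalize_author: input must be character")
  x <- enc2utf8(raw_name)
  x <- tolower(x)
  x <- strip_diacritics(x)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  if (any(!nzchar(x) | is.na(x))) {
    stopf("normalize_author: blank author name at position %s",
          paste(which(!nzchar(x) | is.na(x)), collapse = ", "))
  }
  x
}

# Latin diacritic folding by explicit character map (lower case only; callers
# lower-case first). Multi-character expansions handled separately.
strip_diacritics <- function(x) {
  from <- paste0(
    "àáâãäåāăą", # a
    "çćĉċč",                         # c
    "ďđ",                                           # d
    "èéêëēĕėęě", # e
    "ĝğġģ",                               # g
    "ĥħ",                                           # h
    "ìíîïĩīĭįı", # i
    "ĵ",                                                 # j
    "ķ",                                                 # k
    "ĺļľł",                               # l
    "ñńņň",                               # n
    "òóôõöøōŏő", # o
    "ŕŗř",                                     # r
    "śŝşšș",                         # s
    "ţťŧț",                               # t
    "ùúûüũūŭůűų", # u
    "ŵ",                                                 # w
    "ýÿŷ",                                     # y
    "źżž"                                      # z
  )
  to <- paste0(
    "aaaaaaaaa", "ccccc", "dd", "eeeeeeeee", "gggg", "hh", "iiiiiiiii",
    "j", "k", "llll", "nnnn", "ooooooooo", "rrr", "sssss", "tttt",
    "uuuuuuuuuu", "w", "yyy", "zzz"
  )
  x <- chartr(from, to, x)
  x <- gsub("æ", "ae", x, fixed = TRUE)
  x <- gsub("œ", "oe", x, fixed = TRUE)
  x <- gsub("ß", "ss", x, fixed = TRUE)
  x <- gsub("þ", "th", x, fixed = TRUE)
  x <- gsub("ð", "d", x, fixed = TRUE)
  x
}

#' Construct an author reference
#'
#' @param name author name (normalized with [normalize_author()]).
#' @param countries character vector of ISO 3166-1 alpha-3 affiliation
#'   country codes; may be empty (affiliation country unknown). An author
#'   with institutional affiliations in several countries carries all of
#'   them (set semantics).
#' @return an `author_ref` list with elements `name_key` and `countries`.
#' @export
author_ref <- function(name, countries = character(0)) {
  key <- normalize_author(name)
  if (length(key) != 1) stopf("author_ref: one name at a time")
  countries <- sort(unique(toupper(as.character(countries))))
  structure(list(name_key = key, countries = countries), class = "author_ref")
}

#' Construct a bibliographic record
#'
#' One publication: its identifying metadata, the number of participants
#' enrolled, the countries participants were recruited from, and the ordered
#' author list with per-author affiliation countries.
#'
#' @param record_id unique opaque identifier within a corpus.
#' @param authors list of [author_ref()] objects (non-empty).
#' @param year publication year (integer; not range-checked).
#' @param title,journal free text.
#' @param sample_size number of participants enrolled; `NA` when not
#'   reported, otherwise a non-negative integer.
#' @param enrollment_countries ISO alpha-3 codes of countries participants
#'   were recruited from (distinct from author affiliation countries).
#' @return a `bib_record` list.
#' @export
bib_record <- function(record_id, authors, year = NA_integer_, title = "",
                       journal = "", sample_size = NA_integer_,
                       enrollment_countries = character(0)) {
  if (!is.character(record_id) || length(record_id) != 1 || !nzchar(record_id))
    stopf("bib_record: record_id must be a non-empty string")
  if (!is.list(authors) || length(authors) == 0)
    stopf("bib_record %s: authors must be a non-empty list", record_id)
  if (!all(vapply(authors, inherits, logical(1), "author_ref")))
    stopf("bib_record %s: authors must all be author_ref objects", record_id)
  if (!is.na(sample_size) && !is_count(sample_size))
    stopf("bib_record %s: sample_size must be NA or a non-negative integer",
          record_id)
  structure(list(
    record_id = record_id,
    year = as.integer(year),
    title = as.character(title),
    journal = as.character(journal),
    sample_size = if (is.na(sample_size)) NA_integer_ else as.integer(sample_size),
    enrollment_countries = sort(unique(toupper(as.character(enrollment_countries)))),
    authors = authors
  ), class = "bib_record")
}

#' Assemble records into a validated corpus
#'
#' @param records list of [bib_record()] objects.
#' @param source_id optional label identifying the corpus.
#' @return a `bib_corpus` (list of records with metadata attributes).
#' @export
bib_corpus <- function(records, source_id = "corpus") {
  if (!is.list(records)) stopf("bib_corpus: records must be a list")
  if (!all(vapply(records, inherits, logical(1), "bib_record")))
    stopf("bib_corpus: every element must be a bib_record")
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(ids))
    stopf("bib_corpus: duplicate record_id: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(records, class = "bib_corpus", source_id = source_id)
}

#' @export
print.bib_corpus <- function(x, ...) {
  cat(sprintf("<bib_corpus '%s': %d records, %d distinct authors>\n",
              attr(x, "source_id"), length(x), length(corpus_author_keys(x))))
  invisible(x)
}

# All distinct normalized author keys in a corpus.
corpus_author_keys <- function(corpus) {
  unique(unlist(lapply(corpus, function(r)
    vapply(r$authors, `[[`, character(1), "name_key"))))
}

#' Affiliation countries of a record
#'
#' Union of the author-level affiliation country sets.
#'
#' @param record a `bib_record`.
#' @return sorted character vector of ISO alpha-3 codes (possibly empty).
#' @export
record_countries <- function(record) {
  sort(unique(unlist(lapply(record$authors, `[[`, "countries"))))
}

#' Is a record an international collaboration?
#'
#' A paper is an international scientific collaboration when its authors are
#' affiliated to institutions from at least two different countries (the
#' union of the per-author affiliation country sets has two or more
#' members). Records whose authors all have unknown affiliations are
#' indeterminate and return `NA`.
#'
#' @param record a `bib_record`.
#' @return `TRUE`, `FALSE`, or `NA` (no affiliation country on any author).
#' @export
is_international <- function(record) {
  cc <- record_countries(record)
  if (length(cc) == 0) return(NA)
  length(cc) >= 2
}

#' Load an income-group classification table
#'
#' Reads a CSV with columns `country_code` and `group` mapping ISO alpha-3
#' codes to one of the three World Bank income levels (`low`, `middle`,
#' `high`). Lower- and upper-middle are collapsed into `middle`. Lookups of
#' unmapped countries yield the explicit value `"unknown"`, never a default
#' level.
#'
#' @param path path to the CSV; default is the classification table shipped
#'   with the package (a study-era style World Bank three-level table).
#' @return an `income_table` data frame with attribute `vintage`.
#' @export
load_income_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "income_table.csv", package = "coauthnet",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("country_code", "group") %in% names(df)))
    stopf("income table %s: needs columns country_code, group", path)
  df$country_code <- toupper(trimws(df$country_code))
  df$group <- tolower(trimws(df$group))
  df$group[df$group %in% c("lower-middle", "upper-middle", "lower middle",
                           "upper middle")] <- "middle"
  bad <- !df$group %in% INCOME_LEVELS
  if (any(bad))
    stopf("income table %s: invalid group '%s' (row %d)", path,
          df$group[which(bad)[1]], which(bad)[1])
  if (anyDuplicated(df$country_code))
    stopf("income table %s: duplicate country codes", path)
  structure(df[, c("country_code", "group")], class = c("income_table",
            "data.frame"), vintage = "study-era World Bank three-level table")
}

#' Classify countries into income groups
#'
#' Total function: every input maps to one of `low`, `middle`, `high` or
#' `unknown`; unmapped countries are flagged as `unknown`, never guessed.
#'
#' @param country character vector of ISO alpha-3 codes.
#' @param table an [load_income_table()] table.
#' @return character vector over `{low, middle, high, unknown}`.
#' @examples
#' tab <- load_income_table()
#' classify_country(c("USA", "BRA", "UGA", "XXX"), tab)
#' @export
classify_country <- function(country, table) {
  stopifnot(inherits(table, "income_table"))
  idx <- match(toupper(as.character(country)), table$country_code)
  out <- table$group[idx]
  out[is.na(out)] <- "unknown"
  out
}

# Common country names -> ISO 3166-1 alpha-3, for corpus readers that carry
# names rather than codes. Intentionally small; unmatched names pass through
# upper-cased so that 3-letter codes are always accepted.
COUNTRY_NAME_TO_CODE <- c(
  "united states" = "USA", "united states of america" = "USA", "us" = "USA",
  "usa" = "USA", "united kingdom" = "GBR", "uk" = "GBR",
  "great britain" = "GBR", "south africa" = "ZAF", "brazil" = "BRA",
  "uganda" = "UGA", "kenya" = "KEN", "canada" = "CAN", "france" = "FRA",
  "germany" = "DEU", "italy" = "ITA", "spain" = "ESP", "norway" = "NOR",
  "sweden" = "SWE", "finland" = "FIN", "netherlands" = "NLD",
  "the netherlands" = "NLD", "denmark" = "DNK", "belgium" = "BEL",
  "switzerland" = "CHE", "india" = "IND", "china" = "CHN",
  "thailand" = "THA", "mexico" = "MEX", "chile" = "CHL",
  "argentina" = "ARG", "peru" = "PER", "colombia" = "COL",
  "zambia" = "ZMB", "zimbabwe" = "ZWE", "tanzania" = "TZA",
  "united republic of tanzania" = "TZA", "malawi" = "MWI",
  "senegal" = "SEN", "nigeria" = "NGA", "ghana" = "GHA",
  "rwanda" = "RWA", "burkina faso" = "BFA", "ivory coast" = "CIV",
  "cote d'ivoire" = "CIV", "democratic republic of congo" = "COD",
  "democratic republic of the congo" = "COD",
  "central african republic" = "CAF", "cameroon" = "CMR",
  "mozambique" = "MOZ", "ethiopia" = "ETH", "haiti" = "HTI",
  "cambodia" = "KHM", "vietnam" = "VNM", "viet nam" = "VNM",
  "japan" = "JPN", "south korea" = "KOR", "republic of korea" = "KOR",
  "australia" = "AUS", "new zealand" = "NZL", "austria" = "AUT",
  "portugal" = "PRT", "greece" = "GRC", "ireland" = "IRL",
  "poland" = "POL", "russia" = "RUS", "russian federation" = "RUS",
  "israel" = "ISR", "costa rica" = "CRI", "cuba" = "CUB",
  "honduras" = "HND", "guatemala" = "GTM", "ecuador" = "ECU",
  "bolivia" = "BOL", "venezuela" = "VEN", "indonesia" = "IDN",
  "philippines" = "PHL", "nepal" = "NPL", "bangladesh" = "BGD",
  "pakistan" = "PAK", "morocco" = "MAR", "tunisia" = "TUN",
  "egypt" = "EGY", "mali" = "MLI", "niger" = "NER", "togo" = "TGO",
  "benin" = "BEN", "gambia" = "GMB", "guinea" = "GIN",
  "botswana" = "BWA", "namibia" = "NAM", "lesotho" = "LSO",
  "eswatini" = "SWZ", "swaziland" = "SWZ", "burundi" = "BDI",
  "madagascar" = "MDG", "czech republic" = "CZE", "hungary" = "HUN",
  "romania" = "ROU", "turkey" = "TUR", "iran" = "IRN", "jamaica" = "JAM"
)

#' Convert country names to ISO alpha-3 codes
#'
#' Known common names are mapped; anything else is upper-cased and passed
#' through (so alpha-3 codes are idempotent inputs).
#'
#' @param name character vector of country names or codes.
#' @return character vector of codes.
#' @export
country_code <- function(name) {
  key <- tolower(trimws(as.character(name)))
  mapped <- COUNTRY_NAME_TO_CODE[key]
  out <- ifelse(is.na(mapped), toupper(trimws(as.character(name))), mapped)
  unname(out)
}

# ---- corpus serialization ---------------------------------------------------

# CSV convention (documented for interchange):
#   one row per record; columns record_id, year, title, journal, sample_size,
#   enrollment_countries, authors.
#   enrollment_countries: ";"-separated alpha-3 codes.
#   authors: "|"-separated entries "Name [C1;C2]"; the bracketed country list
#   may be absent or empty ("Name []") when affiliations are unknown. Standard
#   CSV quoting applies to the whole field, so names may contain commas.

format_authors_field <- function(authors) {
  paste(vapply(authors, function(a)
    sprintf("%s [%s]", a$name_key, paste(a$countries, collapse = ";")),
    character(1)), collapse = " | ")
}

parse_authors_field <- function(field, where) {
  parts <- trimws(strsplit(field, "|", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0)
    stopf("%s: record has no authors", where)
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(.*?)\\s*\\[([^]]*)\\]\\s*$", p))[[1]]
    if (length(m) == 3) {
      name <- m[2]
      cc <- trimws(strsplit(m[3], ";", fixed = TRUE)[[1]])
      cc <- cc[nzchar(cc)]
    } else {
      name <- p
      cc <- character(0)
    }
    if (!nzchar(trimws(name))) stopf("%s: author with empty name", where)
    author_ref(name, country_code(cc))
  })
}

#' Write a corpus to CSV
#'
#' @param corpus a `bib_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_corpus_csv()] for the row format.
#' @export
write_corpus_csv <- function(corpus, path) {
  stopifnot(inherits(corpus, "bib_corpus"))
  df <- data.frame(
    record_id = vapply(corpus, `[[`, character(1), "record_id"),
    year = vapply(corpus, `[[`, integer(1), "year"),
    title = vapply(corpus, `[[`, character(1), "title"),
    journal = vapply(corpus, `[[`, character(1), "journal"),
    sample_size = vapply(corpus, `[[`, integer(1), "sample_size"),
    enrollment_countries = vapply(corpus, function(r)
      paste(r$enrollment_countries, collapse = ";"), character(1)),
    authors = vapply(corpus, function(r) format_authors_field(r$authors),
                     character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a corpus from CSV
#'
#' One row per record. `enrollment_countries` is a `;`-separated list of
#' ISO alpha-3 codes; `authors` is a `|`-separated list of
#' `Name [C1;C2]` entries (bracketed affiliation country list, possibly
#' empty). Per-record validation errors are collected and reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @param source_id corpus label; defaults to the file name.
#' @return a `bib_corpus`.
#' @export
read_corpus_csv <- function(path, source_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  needed <- c("record_id", "authors")
  if (!all(needed %in% names(df)))
    stopf("%s: missing required columns: %s", path,
          paste(setdiff(needed, names(df)), collapse = ", "))
  for (col in c("year", "title", "journal", "sample_size",
                "enrollment_countries")) {
    if (!col %in% names(df)) df[[col]] <- ""
  }
  errors <- character(0)
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    where <- sprintf("%s line %d", path, i + 1L)  # +1 for the header row
    rec <- tryCatch({
      ss <- df$sample_size[i] %||% ""
      bib_record(
        record_id = df$record_id[i],
        year = if (nzchar(df$year[i] %||% "")) as.integer(df$year[i]) else NA,
        title = df$title[i] %||% "",
        journal = df$journal[i] %||% "",
        sample_size = if (nzchar(ss)) as.numeric(ss) else NA,
        enrollment_countries = {
          ec <- trimws(strsplit(df$enrollment_countries[i] %||% "", ";")[[1]])
          country_code(ec[nzchar(ec)])
        },
        authors = parse_authors_field(df$authors[i], where)
      )
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", where, conditionMessage(e)))
      NULL
    })
    records[[i]] <- rec
  }
  if (length(errors) > 0)
    stopf("invalid corpus records:\n%s", paste(errors, collapse = "\n"))
  bib_corpus(records, source_id = source_id)
}

#' Write a corpus to JSON
#'
#' @inheritParams write_corpus_csv
#' @export
write_corpus_json <- function(corpus, path) {
  stopifnot(inherits(corpus, "bib_corpus"))
  recs <- lapply(corpus, function(r) list(
    record_id = r$record_id,
    year = r$year,
    title = r$title,
    journal = r$journal,
    sample_size = r$sample_size,
    enrollment_countries = as.list(r$enrollment_countries),
    authors = lapply(r$authors, function(a)
      list(name_key = a$name_key, countries = as.list(a$countries)))
  ))
  jsonlite::write_json(list(source_id = attr(corpus, "source_id"),
                            records = recs),
                       path, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a corpus from JSON
#'
#' @param path JSON file written by [write_corpus_json()] (schema: top-level
#'   `source_id` and `records`, each record mirroring the [bib_record()]
#'   fields, with author objects `{name_key, countries}`).
#' @export
read_corpus_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$records)) stopf("%s: no 'records' field", path)
  errors <- character(0)
  records <- lapply(seq_along(obj$records), function(i) {
    r <- obj$records[[i]]
    tryCatch(
      bib_record(
        record_id = r$record_id %||% "",
        year = r$year %||% NA,
        title = r$title %||% "",
        journal = r$journal %||% "",
        sample_size = r$sample_size %||% NA,
        enrollment_countries = unlist(r$enrollment_countries) %||% character(0),
        authors = lapply(r$authors, function(a)
          author_ref(a$name_key, unlist(a$countries) %||% character(0)))
      ),
      error = function(e) {
        errors <<- c(errors, sprintf("%s record %d: %s", path, i,
                                     conditionMessage(e)))
        NULL
      })
  })
  if (length(errors) > 0)
    stopf("invalid corpus records:\n%s", paste(errors, collapse = "\n"))
  bib_corpus(records, source_id = obj$source_id %||% basename(path))
}
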