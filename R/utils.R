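# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half up
#'
#' Decimal rounding in which exact halves round away from zero
#' (`round_half_up(0.35, 1) == 0.4`), the convention used for the printed
#' percentage tables, as opposed to base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values printed as exact halves survive
  # binary representation error
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# FNV-1a 32-bit string hash, used for salted pseudonyms and config hashes.
# State kept as a double in [0, 2^32); the multiply is split into 16-bit
# halves so every intermediate stays well below 2^53.
fnv1a32 <- function(strings) {
  vapply(strings, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 2166136261
    for (b in bytes) {
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), b)
      hi <- floor(h / 65536)
      lo <- h %% 65536
      h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 2^32
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }, character(1), USE.NAMES = FALSE)
}

# Structure extraction from an igraph object: 1-based integer adjacency list.
# All from-scratch metrics consume this (or the sparse adjacency below), never
# igraph's own metric routines.
adj_list_int <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(el) > 0) {
    both <- rbind(el, el[, 2:1, drop = FALSE])
    spl <- split(both[, 2], both[, 1])
    for (k in names(spl)) adj[[as.integer(k)]] <- as.integer(spl[[k]])
  }
  adj
}

# Sparse symmetric 0/1 adjacency matrix (no self loops, no multiplicities).
adj_sparse <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(n, n)) * 1)
  }
  Matrix::sparseMatrix(i = c(el[, 1], el[, 2]), j = c(el[, 2], el[, 1]),
                       x = 1, dims = c(n, n), use.last.ij = TRUE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
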