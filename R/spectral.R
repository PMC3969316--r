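# Laplacian spectral clustering: eigendecomposition of the graph Laplacian,
# eigengap-based model selection, and k-means partitioning of the spectral
# embedding. Typically applied to the largest connected component of the
# author network.

#' Graph Laplacian
#'
#' `L = D - A` (unnormalized, default) or the symmetric normalized variant
#' `L_sym = I - D^{-1/2} A D^{-1/2}` (rows/columns of isolated nodes are
#' zero). Returned dense and exactly symmetric; rows of the unnormalized
#' Laplacian sum to 0.
#'
#' @param graph an igraph (simple, undirected).
#' @param normalized use the symmetric normalized variant.
#' @return a dense symmetric matrix.
#' @export
graph_laplacian <- function(graph, normalized = FALSE) {
  A <- as.matrix(adj_sparse(graph))
  deg <- rowSums(A)
  if (!normalized) {
    L <- diag(deg, nrow = length(deg)) - A
  } else {
    inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    L <- diag(as.numeric(deg > 0), nrow = length(deg)) -
      outer(inv_sqrt, inv_sqrt) * A
  }
  (L + t(L)) / 2
}

# Ascending eigenvalues/vectors of a symmetric matrix.
laplacian_eigen <- function(L) {
  e <- eigen(L, symmetric = TRUE)
  idx <- rev(seq_along(e$values))
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

#' Choose the number of clusters by the eigengap heuristic
#'
#' Given ascending Laplacian eigenvalues, returns the index `i` (between 1
#' and `k_max - 1`) maximizing the successive gap
#' `lambda[i+1] - lambda[i]`; a large gap after the i-th eigenvalue is the
#' classical indicator that i clusters explain the structure. Ties break
#' toward the smaller k.
#'
#' @param eigenvalues ascending numeric vector (length > `k_max`).
#' @param k_max largest k considered.
#' @return integer k.
#' @export
eigengap_choose_k <- function(eigenvalues, k_max = 25L) {
  if (length(eigenvalues) < 3) stopf("eigengap_choose_k: need >= 3 eigenvalues")
  if (is.unsorted(eigenvalues + 1e-12))
    stopf("eigengap_choose_k: eigenvalues must be ascending")
  k_max <- min(k_max, length(eigenvalues) - 1L)
  gaps <- diff(eigenvalues)[seq_len(k_max - 1L)]
  as.integer(which.max(gaps))
}

#' Laplacian spectral clustering
#'
#' Embeds nodes in the leading (smallest-eigenvalue) eigenvectors of the
#' graph Laplacian and partitions the embedding by k-means. For the
#' unnormalized Laplacian on a connected graph the constant first
#' eigenvector is skipped and eigenvectors 2..k span the embedding; for the
#' normalized variant (or a disconnected graph) eigenvectors 1..k are used,
#' optionally row-normalized. k-means runs with `n_restarts` restarts under
#' a fixed seed, so results are deterministic for a fixed seed.
#'
#' With `k = "auto"`, k is the zero-eigenvalue multiplicity (component
#' count) when the graph is disconnected, and the eigengap choice
#' otherwise. When the relative eigengap at the chosen k is below 0.05 the
#' result is flagged `no_structure` (e.g. complete graphs, where any
#' balanced split is as good as any other).
#'
#' @param graph an igraph; callers normally pass [largest_component()]
#'   output.
#' @param k integer number of clusters (>= 2) or `"auto"`.
#' @param seed RNG seed for k-means restarts.
#' @param normalized use the normalized Laplacian.
#' @param normalize_rows row-normalize the embedding before k-means
#'   (defaults to `normalized`, the usual pairing).
#' @param k_max cap for the eigengap search under `k = "auto"`.
#' @param n_restarts k-means restarts.
#' @return list (class `spectral_result`): `k`, `eigenvalues` (ascending),
#'   `membership` (named, 1-based), `census` (descending cluster sizes),
#'   `no_structure`, `normalized`.
#' @export
spectral_cluster <- function(graph, k = "auto", seed = 20140328,
                             normalized = FALSE,
                             normalize_rows = normalized, k_max = 25L,
                             n_restarts = 10L) {
  n <- igraph::vcount(graph)
  if (n < 2) stopf("spectral_cluster: need at least 2 nodes")
  eig <- laplacian_eigen(graph_laplacian(graph, normalized = normalized))
  ev <- eig$values
  n_zero <- sum(abs(ev) < 1e-8)
  connected <- n_zero <= 1
  auto <- identical(k, "auto")
  if (auto) {
    k <- if (!connected) n_zero else eigengap_choose_k(ev, k_max = min(k_max, n - 1L))
    if (k < 2) k <- 2L
  }
  if (!is_count(k) || k < 2) stopf("spectral_cluster: k must be >= 2 or 'auto'")
  k <- as.integer(k)
  if (k > n) stopf("spectral_cluster: k = %d exceeds node count %d", k, n)
  # unnormalized L on a connected graph: drop the constant first eigenvector
  cols <- if (!normalized && connected) seq(2L, k) else seq_len(k)
  emb <- eig$vectors[, cols, drop = FALSE]
  if (normalize_rows) {
    norms <- sqrt(rowSums(emb^2))
    emb <- emb / ifelse(norms > 0, norms, 1)
  }
  # relative eigengap at the chosen k flags absent structure
  gap_num <- if (k < n) ev[k + 1] - ev[k] else NA_real_
  rel_gap <- if (!is.na(gap_num) && ev[k + 1] > 1e-12) gap_num / ev[k + 1] else 0
  no_structure <- is.na(gap_num) || rel_gap < 0.05
  # Lloyd iterations: spectral embeddings concentrate points into near-
  # duplicates, which trips Hartigan-Wong's transfer-stage heuristics
  km <- with_seed(seed, function()
    suppressWarnings(stats::kmeans(emb, centers = k, nstart = n_restarts,
                                   iter.max = 500L, algorithm = "Lloyd")))
  memb <- km$cluster
  # relabel clusters by decreasing size (ties by first appearance)
  sizes <- tabulate(memb, nbins = k)
  relabel <- order(-sizes, seq_len(k))
  memb <- match(memb, relabel)
  structure(list(
    k = k,
    eigenvalues = ev,
    membership = stats::setNames(as.integer(memb), node_names(graph)),
    census = as.integer(sort(tabulate(memb, nbins = k), decreasing = TRUE)),
    no_structure = no_structure,
    normalized = normalized
  ), class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result: k = %d, census = [%s]%s>\n", x$k,
              paste(x$census, collapse = ", "),
              if (x$no_structure) ", no clear structure" else ""))
  invisible(x)
}
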