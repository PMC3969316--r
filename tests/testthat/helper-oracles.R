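# Independent brute-force oracles. These deliberately use different
# algorithms from the package (Floyd-Warshall instead of BFS, adjacency
# matrix powers instead of Brandes accumulation, explicit triple enumeration
# instead of sparse products, union-find instead of BFS) so agreement is a
# genuine cross-check.

# dense adjacency matrix of an igraph
adj_dense <- function(g) {
  n <- igraph::vcount(g)
  A <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) {
    A[el] <- 1
    A[el[, 2:1, drop = FALSE]] <- 1
  }
  A
}

# all-pairs shortest paths by Floyd-Warshall dynamic programming
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# shortest-path counts sigma[u,v] = number of geodesics, via matrix powers:
# sigma_uv = (A^d(u,v))[u,v]
oracle_sigma <- function(A, D) {
  n <- nrow(A)
  maxd <- max(D[is.finite(D)])
  powers <- vector("list", max(maxd, 1))
  P <- A
  powers[[1]] <- A
  if (maxd >= 2) for (k in 2:maxd) { P <- P %*% A; powers[[k]] <- P }
  S <- matrix(0, n, n)
  diag(S) <- 1
  for (u in seq_len(n)) for (v in seq_len(n)) {
    d <- D[u, v]
    if (u != v && is.finite(d)) S[u, v] <- powers[[d]][u, v]
  }
  S
}

# unnormalized betweenness, unordered pairs once, endpoints excluded, using
# the pair-dependency identity sigma_uv(w) = sigma_uw * sigma_wv when
# d(u,w) + d(w,v) = d(u,v)
oracle_betweenness <- function(g) {
  A <- adj_dense(g)
  n <- nrow(A)
  D <- oracle_floyd_warshall(A)
  S <- oracle_sigma(A, D)
  bc <- numeric(n)
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (!is.finite(D[u, v])) next
    for (w in seq_len(n)) {
      if (w == u || w == v) next
      if (is.finite(D[u, w]) && is.finite(D[w, v]) &&
          D[u, w] + D[w, v] == D[u, v]) {
        bc[w] <- bc[w] + S[u, w] * S[w, v] / S[u, v]
      }
    }
  }
  bc
}

# local clustering by explicit neighbour-pair enumeration
oracle_clustering <- function(g) {
  A <- adj_dense(g)
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      links <- links + A[nb[a], nb[b]]
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# connected components by union-find with path compression
oracle_components <- function(g) {
  n <- igraph::vcount(g)
  parent <- seq_len(n)
  find <- function(x) {
    x <- as.integer(x)
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- as.integer(parent[x])
    }
    x
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  for (e in seq_len(nrow(el))) {
    ra <- find(el[e, 1]); rb <- find(el[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

# exact PageRank by solving the linear system
# (I - d M) x = ((1-d)/n) 1 + d * dangling/n with M the column-stochastic
# walk matrix (dangling columns spread uniformly)
oracle_pagerank <- function(g, damping = 0.85) {
  A <- adj_dense(g)
  n <- nrow(A)
  deg <- rowSums(A)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    if (deg[j] > 0) M[, j] <- A[, j] / deg[j] else M[, j] <- 1 / n
  }
  solve(diag(n) - damping * M, rep((1 - damping) / n, n))
}

# all permutations of 1..k (k small)
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# best label agreement over all permutations of the smaller label set
label_agreement <- function(found, truth) {
  k <- max(truth)
  stopifnot(k <= 6)
  stopifnot(length(found) == length(truth))
  best <- 0
  for (p in all_perms(as.integer(k))) {
    best <- max(best, mean(unname(found) == p[truth]))
  }
  best
}

# random G(n, p) graph with named vertices
random_gnp_named <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  g
}
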