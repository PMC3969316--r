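# From-scratch implementations of the whole-network and per-node statistics
# used in co-authorship analysis: degree, density, connected components,
# shortest-path statistics, clustering coefficients, shortest-path
# betweenness (Brandes' algorithm), PageRank (power iteration), modularity
# and greedy Louvain-style community detection, and discrete maximum-
# likelihood power-law fitting.
#
# All functions consume igraph objects purely as containers: structure is
# extracted as an edge list / adjacency list and every statistic is computed
# here. Graphs are treated as unweighted simple undirected graphs (the
# count-of-collaborators semantics of the reported statistics); edge weights
# are ignored by design.

node_names <- function(graph) {
  igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
}

#' Degree centrality
#'
#' Number of distinct collaborators (links) of each node.
#'
#' @param graph an igraph (simple, undirected).
#' @return named integer vector of degrees.
#' @export
degree_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  stats::setNames(as.integer(deg), node_names(graph))
}

#' Average degree
#'
#' `2|E|/n`: the mean number of collaborators per node.
#'
#' @inheritParams degree_centrality
#' @return a single number.
#' @export
average_degree <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) stopf("average_degree: empty graph")
  2 * igraph::ecount(graph) / n
}

#' Graph density
#'
#' Fraction of realized edges among all `n(n-1)/2` possible node pairs.
#'
#' @inheritParams degree_centrality
#' @return density in `[0, 1]`.
#' @export
graph_density <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2) stopf("graph_density: undefined for fewer than 2 nodes")
  2 * igraph::ecount(graph) / (n * (n - 1))
}

#' Connected components
#'
#' Breadth-first labelling of connected components.
#'
#' @inheritParams degree_centrality
#' @return list with `membership` (named integer labels, 1-based, in order
#'   of discovery from the lowest-index node) and `census` (component sizes,
#'   descending).
#' @export
graph_components <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- adj_list_int(graph)
  membership <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (membership[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    membership[s] <- comp
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[membership[nb] == 0L]
      membership[new] <- comp
      queue <- c(queue, new)
    }
  }
  census <- sort(tabulate(membership, nbins = comp), decreasing = TRUE)
  list(membership = stats::setNames(membership, node_names(graph)),
       census = as.integer(census))
}

# All-pairs shortest-path distances by repeated boolean frontier expansion
# (dense n x n; suitable for the few-thousand-node graphs this package
# targets). Unreachable pairs keep Inf.
all_pairs_dist <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(adj_sparse(graph))
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(1, n)
  k <- 0
  repeat {
    k <- k + 1
    reach_new <- (reach %*% A > 0) * 1
    newly <- reach_new > 0 & D == Inf
    if (!any(newly)) break
    D[newly] <- k
    reach <- ((reach + reach_new) > 0) * 1
    if (k > n) break
  }
  D
}

#' Shortest-path distance statistics
#'
#' Breadth-first distances between all node pairs. The average distance is
#' taken over unordered pairs that are connected (within components), the
#' paper-graph convention for a disconnected network; the diameter is the
#' longest finite distance (the diameter of the largest component when that
#' component realizes the maximum). With `denominator = "giant"` both
#' statistics are computed on the largest component only.
#'
#' @inheritParams degree_centrality
#' @param denominator `"within_components"` (default) or `"giant"`.
#' @return list with `average_distance`, `diameter` (integer) and `n_pairs`
#'   (number of finite unordered pairs averaged over).
#' @export
distance_stats <- function(graph,
                           denominator = c("within_components", "giant")) {
  denominator <- match.arg(denominator)
  if (igraph::vcount(graph) == 0) stopf("distance_stats: empty graph")
  if (igraph::ecount(graph) == 0)
    stopf("distance_stats: graph has no edges, no finite pair distances")
  if (denominator == "giant") graph <- largest_component(graph)
  D <- all_pairs_dist(graph)
  up <- D[upper.tri(D)]
  finite <- up[is.finite(up)]
  list(average_distance = mean(finite),
       diameter = as.integer(max(finite)),
       n_pairs = length(finite))
}

#' Local and global clustering coefficients
#'
#' The local coefficient of a node is the fraction of its neighbour pairs
#' that are themselves connected (triangles through the node over
#' `deg(deg-1)/2`). Nodes of degree below 2 have coefficient 0 and, under
#' the default convention, are included in the global mean (the convention
#' of common network-visualization tools); set
#' `include_low_degree = FALSE` to average over nodes of degree >= 2 only.
#'
#' @inheritParams degree_centrality
#' @param include_low_degree include degree < 2 nodes (as zeros) in the
#'   global mean.
#' @return list with `local` (named numeric vector) and `global_C`.
#' @export
clustering_coefficients <- function(graph, include_low_degree = TRUE) {
  n <- igraph::vcount(graph)
  A <- adj_sparse(graph)
  deg <- Matrix::rowSums(A)
  tri <- Matrix::rowSums((A %*% A) * A) / 2
  local <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  eligible <- if (include_low_degree) rep(TRUE, n) else deg >= 2
  global_C <- if (any(eligible)) mean(local[eligible]) else NaN
  list(local = stats::setNames(as.numeric(local), node_names(graph)),
       global_C = global_C)
}

#' Shortest-path betweenness centrality (Brandes' algorithm)
#'
#' Unnormalized betweenness on the undirected graph: each unordered
#' source-target pair is counted once, endpoints are excluded, and credit is
#' split fractionally across equal-length shortest paths.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- adj_list_int(graph)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    pred <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in pred[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  stats::setNames(bc / 2, node_names(graph))
}

#' PageRank centrality by power iteration
#'
#' Fixed point of the damped random walk on the undirected graph (each edge
#' walkable in both directions). Isolated nodes hold teleport-only mass;
#' the mass a walker would lose on them is redistributed uniformly, so
#' scores always sum to 1.
#'
#' @inheritParams degree_centrality
#' @param damping damping factor in (0, 1).
#' @param tolerance L1 convergence threshold between successive iterates.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   iteration diagnostics.
#' @return named numeric vector summing to 1 (within `tolerance`).
#' @export
pagerank_centrality <- function(graph, damping = 0.85, tolerance = 1e-10,
                                max_iter = 10000L) {
  n <- igraph::vcount(graph)
  if (n == 0) stopf("pagerank_centrality: empty graph")
  if (damping <= 0 || damping >= 1) stopf("pagerank: damping must be in (0,1)")
  A <- adj_sparse(graph)
  deg <- Matrix::rowSums(A)
  dangling <- deg == 0
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    contrib <- x / pmax(deg, 1)
    contrib[dangling] <- 0
    x_new <- (1 - damping) / n +
      damping * (as.numeric(contrib %*% A) + sum(x[dangling]) / n)
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tolerance) {
      return(stats::setNames(x, node_names(graph)))
    }
  }
  stopf("pagerank: no convergence after %d iterations (last delta %.3e, tolerance %.3e)",
        max_iter, delta, tolerance)
}

#' Modularity of a partition
#'
#' Newman-Girvan modularity of a node partition on the unweighted simple
#' graph: the within-community edge fraction minus its expectation under a
#' degree-preserving random null,
#' `Q = sum_c [ m_c/m - (d_c / 2m)^2 ]`.
#'
#' @inheritParams degree_centrality
#' @param membership community labels (vector along vertices, or named).
#' @return Q in `[-0.5, 1]`; a single community gives exactly 0.
#' @export
modularity_q <- function(graph, membership) {
  m <- igraph::ecount(graph)
  if (m == 0) stopf("modularity_q: undefined on an edgeless graph")
  n <- igraph::vcount(graph)
  if (length(membership) != n) stopf("modularity_q: membership length != n")
  memb <- as.integer(factor(membership))
  el <- igraph::as_edgelist(graph, names = FALSE)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  ncomm <- max(memb)
  within <- memb[el[, 1]] == memb[el[, 2]]
  m_in <- tabulate(memb[el[within, 1]], nbins = ncomm)
  d_c <- vapply(seq_len(ncomm), function(cc) sum(deg[memb == cc]), numeric(1))
  sum(m_in / m - (d_c / (2 * m))^2)
}

# One local-moving + aggregation round of the Louvain procedure on a
# weighted graph given as (edge list, weights, n). Self-loops carry the
# aggregated intra-community weight. Returns membership.
louvain_level <- function(el, w, n, resolution, order) {
  # incidence structures
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(j = integer(0), w = numeric(0))
  self_w <- numeric(n)
  strength <- numeric(n)
  for (e in seq_along(w)) {
    a <- el[e, 1]; b <- el[e, 2]
    if (a == b) {
      self_w[a] <- self_w[a] + w[e]
      strength[a] <- strength[a] + 2 * w[e]
    } else {
      adj[[a]]$j <- c(adj[[a]]$j, b); adj[[a]]$w <- c(adj[[a]]$w, w[e])
      adj[[b]]$j <- c(adj[[b]]$j, a); adj[[b]]$w <- c(adj[[b]]$w, w[e])
      strength[a] <- strength[a] + w[e]
      strength[b] <- strength[b] + w[e]
    }
  }
  m2 <- sum(strength)  # = 2m
  comm <- seq_len(n)
  sigma_tot <- strength
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (v in order) {
      cv <- comm[v]
      # weight from v to each neighbouring community
      wc <- numeric(0)
      if (length(adj[[v]]$j)) {
        agg <- tapply(adj[[v]]$w, comm[adj[[v]]$j], sum)
        wc <- as.numeric(agg); names(wc) <- names(agg)
      }
      sigma_tot[cv] <- sigma_tot[cv] - strength[v]
      w_cur <- if (as.character(cv) %in% names(wc)) wc[[as.character(cv)]] else 0
      best_c <- cv
      # gain(C) proportional to w_vC - res * k_v * Sigma_C / 2m
      best_gain <- w_cur - resolution * strength[v] * sigma_tot[cv] / m2
      cand <- sort(unique(as.integer(names(wc))))
      for (cc in cand) {
        if (cc == cv) next
        g <- wc[[as.character(cc)]] -
          resolution * strength[v] * sigma_tot[cc] / m2
        if (g > best_gain + 1e-12 ||
            (abs(g - best_gain) <= 1e-12 && cc < best_c)) {
          best_gain <- g; best_c <- cc
        }
      }
      sigma_tot[best_c] <- sigma_tot[best_c] + strength[v]
      if (best_c != cv) { comm[v] <- best_c; moved <- TRUE; improved_any <- TRUE }
    }
    if (!moved) break
  }
  list(membership = comm, improved = improved_any)
}

#' Greedy modularity community detection (Louvain procedure)
#'
#' Multi-level greedy modularity ascent: nodes are repeatedly moved to the
#' neighbouring community with the largest modularity gain, then communities
#' are aggregated into super-nodes and the process repeats until no gain
#' remains. The node sweep order is drawn under `seed`, making the result
#' deterministic for a fixed seed and stable node ordering; gain ties break
#' toward the smaller community id.
#'
#' @inheritParams degree_centrality
#' @param resolution resolution parameter of the modularity gain (1 =
#'   standard modularity).
#' @param seed RNG seed for the sweep order.
#' @return list (class `partition`) with `membership` (named, 1-based,
#'   relabelled in order of first appearance) and `modularity` (Q of the
#'   returned partition at resolution 1).
#' @export
detect_communities <- function(graph, resolution = 1, seed = 20140328) {
  if (igraph::ecount(graph) == 0)
    stopf("detect_communities: graph has no edges")
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- rep(1, nrow(el))
  node_map <- seq_len(n)  # original node -> current super-node
  with_seed(seed, function() {
    repeat {
      n_cur <- max(node_map)
      order <- sample.int(n_cur)
      lv <- louvain_level(el, w, n_cur, resolution, order)
      comm <- as.integer(factor(lv$membership))
      node_map <<- comm[node_map]
      if (!lv$improved || max(comm) == n_cur) break
      # aggregate communities into super-nodes
      ea <- comm[el[, 1]]; eb <- comm[el[, 2]]
      key <- paste(pmin(ea, eb), pmax(ea, eb))
      agg <- tapply(w, key, sum)
      parts <- strsplit(names(agg), " ", fixed = TRUE)
      el <<- cbind(as.integer(vapply(parts, `[`, character(1), 1)),
                   as.integer(vapply(parts, `[`, character(1), 2)))
      w <<- as.numeric(agg)
    }
  })
  memb <- as.integer(factor(node_map, levels = unique(node_map)))
  structure(list(
    membership = stats::setNames(memb, node_names(graph)),
    modularity = modularity_q(graph, memb)
  ), class = "partition")
}

# Hurwitz-style generalized zeta: sum_{k>=xmin} k^(-alpha), by direct
# summation with an Euler-Maclaurin tail correction.
gen_zeta <- function(alpha, xmin, n_direct = 1e5) {
  stopifnot(alpha > 1, xmin >= 1)
  upper <- xmin + n_direct
  direct <- sum(seq.int(xmin, upper)^(-alpha))
  nn <- upper + 1
  tail <- nn^(1 - alpha) / (alpha - 1) - nn^(-alpha) / 2 +
    alpha * nn^(-alpha - 1) / 12
  direct + tail
}

#' Fit a discrete power law to degree data
#'
#' Discrete maximum-likelihood estimate of the exponent `alpha` of
#' `P(X = k) = k^(-alpha) / zeta(alpha, xmin)` for the tail `k >= xmin`.
#' With `xmin = "auto"`, candidate thresholds are scanned and the one
#' minimizing the Kolmogorov-Smirnov distance between the tail's empirical
#' and fitted CDFs is selected (at least 50 tail observations are required
#' for any candidate). A log-log CCDF regression slope is reported as a
#' secondary diagnostic only; the MLE is the estimate.
#'
#' @param degrees positive integer observations (at least 50).
#' @param xmin integer threshold, or `"auto"`.
#' @return list (class `powerlaw_fit`): `alpha`, `xmin`, `n_tail`, `ks`
#'   (KS statistic), `loglik`, `regression_alpha`, `failed` (logical) and
#'   `reason` when failed. Degenerate inputs (all values identical, or a
#'   tail below 50 points) yield an explicit failed fit, not an error.
#' @export
fit_power_law <- function(degrees, xmin = "auto") {
  x <- as.integer(degrees[degrees > 0 & !is.na(degrees)])
  fail <- function(reason) structure(
    list(alpha = NA_real_, xmin = NA_integer_, n_tail = 0L, ks = NA_real_,
         loglik = NA_real_, regression_alpha = NA_real_, failed = TRUE,
         reason = reason), class = "powerlaw_fit")
  if (length(x) < 50) return(fail("fewer than 50 positive observations"))
  if (length(unique(x)) == 1) return(fail("all values identical"))
  fit_at <- function(xm) {
    tail <- x[x >= xm]
    if (length(tail) < 50 || length(unique(tail)) == 1) return(NULL)
    nll <- function(a) length(tail) * log(gen_zeta(a, xm)) + a * sum(log(tail))
    opt <- stats::optimize(nll, c(1.01, 8))
    a_hat <- opt$minimum
    # KS distance between empirical and fitted tail CDFs
    xs <- seq.int(xm, max(tail))
    pmf <- xs^(-a_hat) / gen_zeta(a_hat, xm)
    cdf_fit <- cumsum(pmf)
    ecdf_tail <- stats::ecdf(tail)
    ks <- max(abs(ecdf_tail(xs) - cdf_fit))
    list(alpha = a_hat, xmin = xm, n_tail = length(tail), ks = ks,
         loglik = -opt$objective)
  }
  if (identical(xmin, "auto")) {
    cands <- sort(unique(x))
    cands <- cands[seq_len(min(length(cands), 50))]
    fits <- Filter(Negate(is.null), lapply(cands, fit_at))
    if (length(fits) == 0) return(fail("no candidate xmin leaves >= 50 tail points"))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
  } else {
    if (!is_count(xmin) || xmin < 1) stopf("fit_power_law: invalid xmin")
    best <- fit_at(as.integer(xmin))
    if (is.null(best)) return(fail("fewer than 50 tail points above xmin"))
  }
  # secondary diagnostic: log-log CCDF regression slope (alpha = 1 - slope)
  tail <- x[x >= best$xmin]
  tt <- sort(unique(tail))
  ccdf <- 1 - stats::ecdf(tail)(tt - 1L)  # P(X >= t)
  keep <- ccdf > 0
  reg <- stats::lm(log(ccdf[keep]) ~ log(tt[keep]))
  structure(c(best, list(regression_alpha = 1 - unname(stats::coef(reg)[2]),
                         failed = FALSE, reason = NA_character_)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (x$failed) cat(sprintf("<powerlaw_fit: FAILED (%s)>\n", x$reason))
  else cat(sprintf(
    "<powerlaw_fit: alpha = %.3f (xmin = %d, n_tail = %d, KS = %.4f)>\n",
    x$alpha, x$xmin, x$n_tail, x$ks))
  invisible(x)
}

#' Rank nodes by a centrality metric
#'
#' Descending ranking with income-group annotation; ties in the metric break
#' lexicographically by node name.
#'
#' @inheritParams degree_centrality
#' @param metric one of `"degree"`, `"betweenness"`, `"pagerank"`.
#' @param top_k number of rows to return.
#' @param damping passed to [pagerank_centrality()] when
#'   `metric = "pagerank"`.
#' @return data frame with `rank`, `name`, `value`, `income_group`.
#' @export
rank_authors <- function(graph, metric = c("degree", "betweenness", "pagerank"),
                         top_k = 10L, damping = 0.85) {
  metric <- match.arg(metric)
  values <- switch(metric,
    degree = degree_centrality(graph),
    betweenness = betweenness_centrality(graph),
    pagerank = pagerank_centrality(graph, damping = damping))
  nm <- node_names(graph)
  inc <- igraph::V(graph)$income_group %||% rep(NA_character_, length(nm))
  ord <- order(-values, nm)
  take <- utils::head(ord, top_k)
  data.frame(rank = seq_along(take), name = nm[take],
             value = unname(values[take]), income_group = inc[take],
             metric = metric, stringsAsFactors = FALSE)
}
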