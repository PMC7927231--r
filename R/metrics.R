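metric_value <- function(name, value, per_node = NULL, per_edge = NULL,
                         defined = TRUE) {
  structure(list(name = name, value = value, per_node = per_node,
                 per_edge = per_edge, defined = defined),
            class = "metric_value")
}

#' @export
print.metric_value <- function(x, ...) {
  cat(sprintf("<metric_value> %s = %s\n", x$name,
              if (x$defined) format(x$value) else "undefined"))
  invisible(x)
}

as_adj <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  net$adjacency
}

#' Transitivity of a binary network
#'
#' Ratio of three times the number of triangles to the number of connected
#' triplets: `sum(2 t_i) / sum(k_i (k_i - 1))`. Zero (with a warning) when
#' the graph has no connected triplet.
#'
#' @param net A `binary_network`.
#' @return A `metric_value` in `[0, 1]`.
#' @export
net_transitivity <- function(net) {
  A <- as_adj(net)
  if (nrow(A) < 3) stopf("transitivity needs at least 3 nodes")
  deg <- rowSums(A)
  if (all(deg < 2)) warning("no connected triplets; transitivity set to 0")
  metric_value("transitivity", cpp_transitivity(A))
}

#' Mean clustering coefficient
#'
#' Per node: the fraction of neighbour pairs that are themselves
#' connected, `2 t_i / (k_i (k_i - 1))`, defined as 0 for degree < 2; the
#' scalar value is the mean over nodes.
#'
#' @param net A `binary_network`.
#' @return A `metric_value` with a `per_node` vector.
#' @export
net_clustering <- function(net) {
  A <- as_adj(net)
  if (nrow(A) < 3) stopf("clustering needs at least 3 nodes")
  cc <- cpp_clustering(A)
  names(cc) <- net$regions
  metric_value("clustering", mean(cc), per_node = cc)
}

#' Degree assortativity
#'
#' Pearson correlation between the degrees at the two ends of every edge
#' (each edge contributing both orientations). Undefined on regular
#' graphs (zero degree variance): returned with `defined = FALSE` and an
#' `NA` value.
#'
#' @param net A `binary_network`.
#' @return A `metric_value` in `[-1, 1]` or undefined.
#' @export
net_assortativity <- function(net) {
  A <- as_adj(net)
  if (sum(A) < 4) stopf("assortativity needs at least 2 edges")
  a <- cpp_assortativity(A)
  if (is.na(a)) metric_value("assortativity", NA_real_, defined = FALSE)
  else metric_value("assortativity", a)
}

#' Node and edge betweenness centrality
#'
#' Brandes accumulation over unweighted shortest paths. Node betweenness
#' excludes path endpoints and, when `normalized`, is divided by
#' `(n-1)(n-2)/2` (the number of pairs that could route through a node);
#' edge betweenness is divided by `n(n-1)/2`. Scalar summaries are the
#' means over nodes and over present edges.
#'
#' @param net A connected `binary_network`.
#' @param normalized Divide by the pair-count denominators (default).
#' @return List with elements `node` and `edge`, each a `metric_value`
#'   (`per_node` vector / `per_edge` matrix).
#' @export
net_betweenness <- function(net, normalized = TRUE) {
  A <- as_adj(net)
  n <- nrow(A)
  b <- cpp_betweenness(A)
  node <- b$node
  edge <- b$edge
  if (normalized) {
    node <- node / ((n - 1) * (n - 2) / 2)
    edge <- edge / (n * (n - 1) / 2)
  }
  names(node) <- net$regions
  dimnames(edge) <- list(net$regions, net$regions)
  edge_vals <- edge[upper.tri(edge) & A == 1]
  list(node = metric_value("node_betweenness", mean(node), per_node = node),
       edge = metric_value("edge_betweenness", mean(edge_vals),
                           per_edge = edge))
}

#' Louvain community detection and modularity
#'
#' Multi-level Louvain optimization with a random node sweep order per
#' restart; the best partition over `n_restarts` seeded restarts is
#' returned with its Newman modularity `Q = sum_c [e_c/m - (d_c/2m)^2]`
#' recomputed on the original binary graph. Deterministic given `seed`.
#'
#' @param net A connected `binary_network`.
#' @param n_restarts Number of restarts (default 20; Louvain is sweep-
#'   order dependent and the permutation engine needs reproducibility).
#' @param seed Integer seed for the restart shuffles.
#' @return A `partition`: `membership` (community ids contiguous from 0,
#'   named by region) and `Q`.
#' @export
net_modularity <- function(net, n_restarts = 20, seed = 1) {
  A <- as_adj(net)
  res <- cpp_louvain(A, as.integer(n_restarts), as.integer(seed))
  membership <- res$membership
  names(membership) <- net$regions
  structure(list(membership = membership, Q = res$Q), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d communities, Q = %.4f\n",
              length(unique(x$membership)), x$Q))
  invisible(x)
}

#' Modularity of a given partition
#'
#' @param net A `binary_network`.
#' @param membership Integer community ids (0-based or any coding).
#' @return Newman modularity of the partition on `net`.
#' @export
modularity_value <- function(net, membership) {
  A <- as_adj(net)
  m <- as.integer(as.integer(factor(membership)) - 1L)
  cpp_modularity(A, m)
}

metric_want <- function(metrics) {
  bad <- setdiff(metrics, metric_names())
  if (length(bad)) stopf("unknown metric(s): %s", paste(bad, collapse = ", "))
  metric_names() %in% metrics
}

#' Metric curves across a density sweep
#'
#' One value per metric per density, in sweep order. An undefined
#' assortativity at some density is recorded as `NA` there.
#'
#' @param sweep A `density_sweep`.
#' @param metrics Subset of [metric_names()].
#' @param n_restarts,seed Louvain settings (see [net_modularity()]).
#' @return A `metric_curves` object: `densities` plus a densities x
#'   metrics value matrix.
#' @export
metric_curves <- function(sweep, metrics = metric_names(), n_restarts = 20,
                          seed = 1) {
  stopifnot(inherits(sweep, "density_sweep"))
  want <- metric_want(metrics)
  D <- length(sweep$networks)
  vals <- matrix(NA_real_, D, length(metric_names()),
                 dimnames = list(format(sweep$densities), metric_names()))
  for (d in seq_len(D)) {
    net <- sweep$networks[[d]]
    A <- net$adjacency
    n <- nrow(A)
    if (want[1])
      vals[d, 1] <- net_modularity(net, n_restarts,
                                   split_seed(seed, paste0("d", d)))$Q
    if (want[2]) vals[d, 2] <- cpp_transitivity(A)
    if (want[3]) vals[d, 3] <- cpp_assortativity(A)
    if (want[4]) vals[d, 4] <- mean(cpp_clustering(A))
    if (want[5] || want[6]) {
      b <- net_betweenness(net)
      if (want[5]) vals[d, 5] <- b$node$value
      if (want[6]) vals[d, 6] <- b$edge$value
    }
    if (want[7]) vals[d, 7] <- mean(rowSums(A))
  }
  structure(list(densities = sweep$densities,
                 values = vals[, metrics, drop = FALSE]),
            class = "metric_curves")
}

#' @export
print.metric_curves <- function(x, ...) {
  cat("<metric_curves>\n")
  print(round(x$values, 4))
  invisible(x)
}
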