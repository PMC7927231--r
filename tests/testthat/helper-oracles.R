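# Independent brute-force references for the graph metrics, plus small
# fixture builders.  Everything here is deliberately naive (triple loops,
# explicit path enumeration, full partition enumeration) so it shares no
# code path with the implementation it checks.

# -- fixtures ------------------------------------------------------------

rand_connected_adj <- function(n, p = 0.45) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(runif(length(up)) < p)
    A <- A + t(A)
    if (r_connected(A)) return(A)
  }
}

r_connected <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

adj_to_network <- function(A) {
  n <- nrow(A)
  regions <- sprintf("r%02d", seq_len(n))
  dimnames(A) <- list(regions, regions)
  structure(list(adjacency = A, density = sum(A) / (n * (n - 1)),
                 n_edges = sum(A) / 2, regions = regions),
            class = "binary_network")
}

graph_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  adj_to_network(A)
}

complete_network <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  adj_to_network(A)
}

star_network <- function(n_leaves) {
  graph_from_edges(n_leaves + 1, lapply(seq_len(n_leaves) + 1,
                                        function(j) c(1, j)))
}

path_network <- function(n) {
  graph_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

cycle_network <- function(n) {
  graph_from_edges(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1)),
                        list(c(n, 1))))
}

# morph_dataset from a raw values matrix (bypasses the generator)
make_dataset <- function(values, group, age = NULL, sex = NULL,
                         scores = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%03d", seq_len(n))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("region%03d", seq_len(ncol(values)))
  if (is.null(age)) age <- seq(25, 45, length.out = n)
  if (is.null(sex)) sex <- rep_len(c(0L, 1L), n)
  if (is.null(scores))
    scores <- data.frame(row.names = rownames(values))
  structure(list(values = values, regions = colnames(values),
                 modality = "cortical_thickness",
                 group = factor(group, levels = unique(group)),
                 age = age, sex = sex, scores = scores,
                 residualized = FALSE, generator = NULL),
            class = "morph_dataset")
}

# -- metric oracles ------------------------------------------------------

oracle_transitivity <- function(A) {
  n <- nrow(A)
  tri <- 0
  triplets <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      for (k in seq_len(n)) {
        if (i < j && j < k && A[i, j] && A[j, k] && A[i, k]) tri <- tri + 1
        # ordered centre j with two distinct neighbours i, k
        if (i != j && k != j && i < k && A[i, j] && A[j, k])
          triplets <- triplets + 1
      }
  if (triplets == 0) return(0)
  3 * tri / triplets
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_along(nb))
      for (b in seq_along(nb))
        if (a < b && A[nb[a], nb[b]]) links <- links + 1
    2 * links / (k * (k - 1))
  })
}

oracle_assortativity <- function(A) {
  deg <- rowSums(A)
  xs <- c()
  ys <- c()
  n <- nrow(A)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && A[i, j]) {
        xs <- c(xs, deg[i])
        ys <- c(ys, deg[j])
      }
  if (var(xs) == 0) return(NA_real_)
  mean_x <- mean(xs)
  cov_xy <- mean(xs * ys) - mean_x^2
  var_x <- mean(xs^2) - mean_x^2
  cov_xy / var_x
}

# all shortest paths between a pair by explicit depth-limited enumeration
all_shortest_paths_r <- function(A, s, t) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  while (length(frontier) && !is.finite(dist[t])) {
    nxt <- setdiff(which(colSums(A[frontier, , drop = FALSE]) > 0),
                   which(is.finite(dist)))
    dist[nxt] <- dist[frontier[1]] + 1
    frontier <- nxt
  }
  if (!is.finite(dist[t])) return(list())
  paths <- list()
  extend <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (u in which(A[v, ] == 1))
      if (dist[u] == dist[v] + 1) extend(c(path, u))
  }
  extend(s)
  paths
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  node <- rep(0, n)
  edge <- matrix(0, n, n)
  for (s in seq_len(n - 1))
    for (t in seq(s + 1, n)) {
      paths <- all_shortest_paths_r(A, s, t)
      np <- length(paths)
      if (np == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        node[inner] <- node[inner] + 1 / np
        for (k in seq_len(length(p) - 1)) {
          edge[p[k], p[k + 1]] <- edge[p[k], p[k + 1]] + 1 / np
          edge[p[k + 1], p[k]] <- edge[p[k + 1], p[k]] + 1 / np
        }
      }
    }
  list(node = node, edge = edge)
}

# modularity of a membership vector, independent formulation
oracle_modularity <- function(A, memb) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  same <- outer(memb, memb, "==")
  sum((A - outer(deg, deg) / (2 * m)) * same) / (2 * m)
}

# all set partitions of n elements as membership vectors (Bell(n) of them)
set_partitions <- function(n) {
  parts <- list(1L)
  for (el in seq_len(n)[-1]) {
    nxt <- list()
    for (p in parts) {
      for (b in seq_len(max(p) + 1L))
        nxt[[length(nxt) + 1L]] <- c(p, b)
    }
    parts <- nxt
  }
  parts
}

oracle_best_modularity <- function(A) {
  best <- -Inf
  for (memb in set_partitions(nrow(A))) {
    q <- oracle_modularity(A, memb)
    if (q > best) best <- q
  }
  best
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cv / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
          sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# BH step-up oracle: q_i = min over j >= rank(i) of p_(j) * m / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# MST-first greedy thresholding, independent R implementation
oracle_threshold <- function(R, m_target) {
  n <- nrow(R)
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  w <- R[pairs]
  ord <- order(-w, pairs[, 1], pairs[, 2])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  chosen <- matrix(0L, n, n)
  n_chosen <- 0
  for (idx in ord) {
    ri <- find(pairs[idx, 1])
    rj <- find(pairs[idx, 2])
    if (ri != rj) {
      parent[ri] <- rj
      chosen[pairs[idx, 1], pairs[idx, 2]] <- 1L
      chosen[pairs[idx, 2], pairs[idx, 1]] <- 1L
      n_chosen <- n_chosen + 1
      if (n_chosen == n - 1) break
    }
  }
  for (idx in ord) {
    if (n_chosen >= m_target) break
    i <- pairs[idx, 1]
    j <- pairs[idx, 2]
    if (chosen[i, j] == 1L) next
    if (R[i, j] <= 0) next
    chosen[i, j] <- 1L
    chosen[j, i] <- 1L
    n_chosen <- n_chosen + 1
  }
  chosen
}
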