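test_that("closed-form values on canonical graphs", {
  k5 <- complete_network(5)
  expect_equal(net_transitivity(k5)$value, 1.0)
  expect_equal(net_clustering(k5)$value, 1.0)

  p4 <- path_network(4)
  expect_equal(net_transitivity(p4)$value, 0.0)

  s6 <- star_network(5)  # hub + 5 leaves
  expect_equal(net_assortativity(s6)$value, -1.0)
  expect_equal(net_clustering(s6)$value, 0.0)
  b <- net_betweenness(s6)
  expect_equal(unname(b$node$per_node[1]), 1.0)       # hub carries all pairs
  expect_equal(unname(b$node$per_node[2:6]), rep(0, 5))

  c5 <- cycle_network(5)  # regular: assortativity undefined
  a <- net_assortativity(c5)
  expect_false(a$defined)
  expect_true(is.na(a$value))

  p3 <- path_network(3)
  expect_equal(unname(net_betweenness(p3)$node$per_node), c(0, 1, 0))
})

test_that("Louvain finds the planted two-clique split with exact Q", {
  edges <- c(lapply(combn(1:5, 2, simplify = FALSE), identity),
             lapply(combn(6:10, 2, simplify = FALSE), identity),
             list(c(5, 6)))
  net <- graph_from_edges(10, edges)
  p <- net_modularity(net, n_restarts = 20, seed = 3)
  expect_equal(length(unique(p$membership)), 2L)
  expect_equal(unname(p$membership[1:5]), rep(p$membership[[1]], 5))
  # m = 21, each clique: 10 internal edges, total degree 21
  q_exact <- 2 * (10 / 21 - (21 / 42)^2)
  expect_equal(p$Q, q_exact, tolerance = 1e-12)
  expect_equal(modularity_value(net, p$membership), p$Q, tolerance = 1e-12)

  k6 <- complete_network(6)
  pk <- net_modularity(k6, seed = 1)
  expect_equal(length(unique(pk$membership)), 1L)
  expect_equal(pk$Q, 0.0)
})

test_that("metrics match brute-force enumeration on small random graphs", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    A <- rand_connected_adj(n)
    net <- adj_to_network(A)

    expect_equal(net_transitivity(net)$value, oracle_transitivity(A),
                 tolerance = 1e-10)
    expect_equal(unname(net_clustering(net)$per_node), oracle_clustering(A),
                 tolerance = 1e-10)
    expect_equal(net_assortativity(net)$value, oracle_assortativity(A),
                 tolerance = 1e-10)

    b <- net_betweenness(net, normalized = FALSE)
    ob <- oracle_betweenness(A)
    expect_equal(unname(b$node$per_node), ob$node, tolerance = 1e-10)
    expect_equal(unname(b$edge$per_edge), ob$edge, tolerance = 1e-10)

    p <- net_modularity(net, n_restarts = 10, seed = i)
    expect_equal(modularity_value(net, p$membership), p$Q,
                 tolerance = 1e-12)
    expect_gte(p$Q, 0.97 * oracle_best_modularity(A) - 1e-12)
  }
})

test_that("scalar metrics are invariant under node relabelling", {
  set.seed(42)
  A <- rand_connected_adj(12)
  perm <- sample(12)
  B <- A[perm, perm]
  n1 <- adj_to_network(A)
  n2 <- adj_to_network(B)
  expect_equal(net_transitivity(n2)$value, net_transitivity(n1)$value)
  expect_equal(net_clustering(n2)$value, net_clustering(n1)$value)
  expect_equal(net_assortativity(n2)$value, net_assortativity(n1)$value)
  expect_equal(net_betweenness(n2)$node$value,
               net_betweenness(n1)$node$value)
  expect_equal(net_modularity(n2, 20, 1)$Q, net_modularity(n1, 20, 1)$Q,
               tolerance = 1e-12)
})

test_that("metrics agree with igraph on a study-sized network", {
  skip_if_not_installed("igraph")
  d <- generate_cohort(cohort_spec(seed = 9))
  a <- association_matrix(residualize(d), "HC")
  net <- threshold_at_density(a, 0.25)
  g <- igraph::graph_from_adjacency_matrix(net$adjacency,
                                           mode = "undirected")
  expect_equal(net_transitivity(net)$value,
               igraph::transitivity(g, type = "global"), tolerance = 1e-12)
  expect_equal(net_clustering(net)$value,
               igraph::transitivity(g, type = "localaverage",
                                    isolates = "zero"), tolerance = 1e-12)
  expect_equal(net_assortativity(net)$value,
               igraph::assortativity_degree(g), tolerance = 1e-12)
  b <- net_betweenness(net, normalized = FALSE)
  expect_equal(unname(b$node$per_node), unname(igraph::betweenness(g)),
               tolerance = 1e-10)
  el <- igraph::as_edgelist(g, names = FALSE)
  expect_equal(unname(b$edge$per_edge[el]),
               unname(igraph::edge_betweenness(g)), tolerance = 1e-10)
})

test_that("metric curves follow the sweep and flag undefined values", {
  a <- local({
    set.seed(43)
    X <- matrix(rnorm(15 * 10), 15, 10)
    R <- cor(X)
    diag(R) <- 0
    regions <- sprintf("r%02d", 1:10)
    dimnames(R) <- list(regions, regions)
    structure(list(r = R, group = "A", n_subjects = 15L,
                   regions = regions), class = "assoc_matrix")
  })
  sw <- density_sweep(a, c(0.3, 1.0), ranking = "absolute")
  mc <- metric_curves(sw, c("modularity", "transitivity", "assortativity"),
                      seed = 1)
  # complete-graph endpoint: closure is total, no community structure,
  # assortativity undefined on a regular graph
  expect_equal(unname(mc$values["1.0", "transitivity"]), 1.0)
  expect_equal(unname(mc$values["1.0", "modularity"]), 0.0)
  expect_true(is.na(mc$values["1.0", "assortativity"]))
  mc2 <- metric_curves(sw, c("modularity", "transitivity", "assortativity"),
                       seed = 1)
  expect_identical(mc$values, mc2$values)
})

test_that("metric values respect their theoretical bounds", {
  set.seed(44)
  for (i in 1:20) {
    A <- rand_connected_adj(sample(5:12, 1), p = runif(1, 0.3, 0.8))
    net <- adj_to_network(A)
    expect_true(net_transitivity(net)$value >= 0 &&
                  net_transitivity(net)$value <= 1)
    expect_true(net_clustering(net)$value >= 0 &&
                  net_clustering(net)$value <= 1)
    av <- net_assortativity(net)$value
    expect_true(is.na(av) || (av >= -1 - 1e-12 && av <= 1 + 1e-12))
    q <- net_modularity(net, 5, i)$Q
    expect_true(q >= -0.5 && q <= 1)
  }
})
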