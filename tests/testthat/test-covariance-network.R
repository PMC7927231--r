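test_that("residualization removes covariate effects within group", {
  set.seed(21)
  n <- 24
  age <- runif(n, 20, 60)
  sex <- rep_len(c(0L, 1L), n)
  vals <- matrix(rnorm(n * 5, 2.5, 0.1), n, 5)
  vals[, 2] <- 0.01 * age + 1.7           # exact linear function of age
  d <- make_dataset(vals, rep(c("A", "B"), each = 12), age = age, sex = sex)

  r <- residualize(d)
  for (g in c("A", "B")) {
    rows <- d$group == g
    expect_lt(max(abs(colMeans(r$values[rows, ]))), 1e-12)
    expect_lt(max(abs(cor(r$values[rows, 1], age[rows]))), 1e-10)
  }
  expect_lt(max(abs(r$values[, 2])), 1e-10)  # perfect fit -> zero residuals

  # idempotence
  r2 <- residualize(r)
  expect_equal(r2$values, r$values, tolerance = 1e-12)

  # intercept-only = within-group demeaning
  r0 <- residualize(d, character(0))
  rows <- d$group == "A"
  expect_equal(r0$values[rows, ],
               sweep(d$values[rows, ], 2, colMeans(d$values[rows, ])),
               tolerance = 1e-12)
})

test_that("residualization rejects collinear covariates and tiny groups", {
  vals <- matrix(rnorm(40), 8, 5)
  d <- make_dataset(vals, rep("A", 8), sex = rep(1L, 8))  # sex constant
  expect_error(residualize(d), "rank-deficient")
  d2 <- make_dataset(matrix(rnorm(15), 3, 5), rep("A", 3))
  expect_error(residualize(d2), "need more than")
})

test_that("association matrix equals a hand-computed Pearson matrix", {
  set.seed(22)
  vals <- matrix(rnorm(20, 2.5, 0.2), 5, 4)
  d <- make_dataset(vals, rep("A", 5))
  a <- association_matrix(d, "A")
  for (i in 1:3)
    for (j in (i + 1):4)
      expect_equal(a$r[i, j], oracle_pearson(vals[, i], vals[, j]),
                   tolerance = 1e-12)
  expect_identical(a$r, t(a$r))
  expect_true(all(diag(a$r) == 0))
  expect_true(all(abs(a$r) <= 1))
  expect_equal(a$n_subjects, 5L)
})

test_that("association matrix: duplicates, affine invariance, errors", {
  set.seed(23)
  vals <- matrix(rnorm(40, 2.5, 0.2), 10, 4)
  vals[, 4] <- vals[, 1]  # exact duplicate region
  d <- make_dataset(vals, rep("A", 10))
  a <- association_matrix(d, "A")
  expect_equal(a$r[1, 4], 1.0, tolerance = 1e-12)

  # Pearson invariance under affine rescaling of a column
  vals2 <- vals
  vals2[, 2] <- 3.7 * vals2[, 2] - 11
  a2 <- association_matrix(make_dataset(vals2, rep("A", 10)), "A")
  expect_equal(a2$r, a$r, tolerance = 1e-12)

  vals3 <- vals
  vals3[, 3] <- 2.5
  expect_error(association_matrix(make_dataset(vals3, rep("A", 10)), "A"),
               "zero-variance.*region003")
  expect_error(association_matrix(make_dataset(vals[1:3, ], rep("A", 3)),
                                  "A"), "at least 4")
  expect_error(association_matrix(d, "Z"), "unknown group")
})

make_assoc <- function(R, group = "A", n_subjects = 20L) {
  regions <- sprintf("r%02d", seq_len(nrow(R)))
  dimnames(R) <- list(regions, regions)
  structure(list(r = R, group = group, n_subjects = n_subjects,
                 regions = regions), class = "assoc_matrix")
}

# factor-driven correlations: mostly positive, like real structural
# covariance matrices (positive ranking needs enough candidate edges)
rand_assoc <- function(n, seed, n_sub = 40) {
  set.seed(seed)
  f <- rnorm(n_sub)
  X <- outer(f, runif(n, 0.8, 1.2)) + 0.6 * matrix(rnorm(n_sub * n),
                                                   n_sub, n)
  R <- cor(X)
  diag(R) <- 0
  make_assoc(R)
}

test_that("density thresholding yields connected networks of exact size", {
  a <- rand_assoc(16, seed = 31)
  full <- threshold_at_density(a, 1.0)
  expect_true(all(full$adjacency[upper.tri(full$adjacency)] == 1))

  tree <- threshold_at_density(a, 2 / 16)  # minimal connected density
  expect_equal(tree$n_edges, 15L)
  expect_true(r_connected(tree$adjacency))

  for (dd in c(0.2, 0.35, 0.6)) {
    net <- threshold_at_density(a, dd)
    expect_equal(sum(net$adjacency) / 2, round(dd * 16 * 15 / 2))
    expect_true(r_connected(net$adjacency))
    expect_true(all(diag(net$adjacency) == 0))
  }
  expect_error(threshold_at_density(a, 0.05), "minimal connected density")
})

test_that("thresholding matches the brute-force MST-first greedy rule", {
  set.seed(32)
  for (rep in 1:5) {
    f <- rnorm(10)
    X <- outer(f, runif(6, 0.8, 1.2)) + 0.8 * matrix(rnorm(60), 10, 6)
    R <- cor(X)
    diag(R) <- 0
    a <- make_assoc(R)
    m_target <- round(0.4 * 15)
    net <- threshold_at_density(a, 0.4)
    expect_equal(unname(net$adjacency), oracle_threshold(R, m_target))
  }
})

test_that("density sweeps are nested with prescribed edge counts", {
  a <- rand_assoc(68, seed = 33)
  sw <- density_sweep(a, seq(0.1, 0.5, by = 0.05))
  counts <- vapply(sw$networks, function(n) n$n_edges, integer(1))
  expect_equal(counts, as.integer(round(seq(0.1, 0.5, by = 0.05) * 2278)))
  expect_equal(counts[c(1, 9)], c(228L, 1139L))
  for (k in 2:length(sw$networks)) {
    lo <- sw$networks[[k - 1]]$adjacency
    hi <- sw$networks[[k]]$adjacency
    expect_true(all(hi[lo == 1] == 1))  # nestedness
    expect_true(r_connected(hi))
  }
  one <- density_sweep(a, 0.3)
  expect_identical(one$networks[[1]]$adjacency,
                   threshold_at_density(a, 0.3)$adjacency)
  expect_error(density_sweep(a, c(0.3, 0.2)), "strictly increasing")
})

test_that("tie-breaking is lexicographic and runs are bit-reproducible", {
  R <- matrix(0.5, 5, 5)  # all weights tied
  diag(R) <- 0
  a <- make_assoc(R)
  net <- threshold_at_density(a, 2 / 5)
  # MST of an all-tied matrix by (i, j) order: star on node 1
  expect_equal(unname(net$adjacency[1, ]), c(0L, 1L, 1L, 1L, 1L))
  expect_identical(threshold_at_density(a, 0.6)$adjacency,
                   threshold_at_density(a, 0.6)$adjacency)
})
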