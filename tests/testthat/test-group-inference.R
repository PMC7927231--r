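# small two-group dataset from one generating spec (true null unless an
# effect is planted)
null_cohort <- function(seed, n_regions = 19, sizes = c(A = 12, B = 10)) {
  generate_cohort(cohort_spec(group_sizes = sizes, n_regions = n_regions,
                              modality = "subcortical_volume",
                              latent_dim = 4, seed = seed))
}

test_that("percentile p-value follows the add-one two-tailed formula", {
  expect_equal(sconet:::perm_pvalue(0.25, c(0.1, -0.2, 0.3, -0.05)),
               2 / 5)
  expect_equal(sconet:::perm_pvalue(0, rnorm(99)), 1)
  # minimum attainable p is 1/(n_perm + 1)
  expect_equal(sconet:::perm_pvalue(10, runif(499)), 1 / 500)
})

test_that("BH adjustment matches the hand step-up, with edge cases", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))  # constant unchanged
  expect_equal(fdr_adjust(0.37), 0.37)                # singleton
  set.seed(51)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  p_na <- c(0.01, NA, 0.5)
  q_na <- fdr_adjust(p_na)
  expect_true(is.na(q_na[2]))
  expect_equal(q_na[c(1, 3)], oracle_bh(p_na[c(1, 3)]))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust("a"), "numeric")
})

test_that("permutation test output obeys its contracts", {
  d <- null_cohort(seed = 52)
  res <- permutation_test(d, "A", "B",
                          metrics = c("transitivity", "assortativity"),
                          densities = c(0.2, 0.3, 0.4), n_perm = 100,
                          seed = 3)
  expect_s3_class(res, "difference_result")
  expect_equal(dim(res$observed), c(3L, 2L))
  expect_equal(dim(res$null), c(100L, 3L, 2L))
  ok <- !is.na(res$p)
  expect_true(all(res$p[ok] >= 1 / 101 & res$p[ok] <= 1))
  expect_true(all(res$q[ok] >= res$p[ok] - 1e-12))
  expect_true(all(res$q[ok] <= 1))

  res2 <- permutation_test(d, "A", "B",
                           metrics = c("transitivity", "assortativity"),
                           densities = c(0.2, 0.3, 0.4), n_perm = 100,
                           seed = 3)
  expect_identical(res$observed, res2$observed)
  expect_identical(res$p, res2$p)
})

test_that("swapping the groups negates the difference and keeps p", {
  d <- null_cohort(seed = 53)
  args <- list(metrics = "transitivity", densities = c(0.2, 0.4),
               n_perm = 100, seed = 9)
  ab <- do.call(permutation_test, c(list(d, "A", "B"), args))
  ba <- do.call(permutation_test, c(list(d, "B", "A"), args))
  expect_equal(ba$observed, -ab$observed)
  expect_identical(ba$p, ab$p)
  expect_identical(ba$q, ab$q)
})

test_that("permutation test validates its inputs", {
  d <- null_cohort(seed = 54)
  expect_error(permutation_test(d, "A", "Z", n_perm = 100), "unknown group")
  expect_error(permutation_test(d, "A", "B", n_perm = 10), "n_perm")
  tiny <- make_dataset(matrix(rnorm(60, 2, 0.1), 6, 10),
                       c(rep("A", 3), rep("B", 3)))
  expect_error(permutation_test(tiny, "A", "B", n_perm = 100),
               "at least 4")
})

test_that("NBS extracts suprathreshold components as drawn by hand", {
  # 4-node statistic matrix: edges 1-2 (5), 3-4 (5), 1-3 (0.1)
  s <- matrix(0, 4, 4)
  s[1, 2] <- s[2, 1] <- 5
  s[3, 4] <- s[4, 3] <- 5
  s[1, 3] <- s[3, 1] <- 0.1
  cmp <- sconet:::cpp_nbs_components(s, 3)
  expect_equal(length(cmp$extent), 2L)
  expect_equal(cmp$extent, c(1, 1))
  expect_equal(cmp$component, c(1L, 1L, 2L, 2L))

  # threshold below 0.1 merges everything into one 3-edge component
  cmp2 <- sconet:::cpp_nbs_components(s, 0.05)
  expect_equal(length(cmp2$extent), 1L)
  expect_equal(cmp2$extent, 3)
  expect_equal(sconet:::cpp_nbs_max_extent(s, 0.05, FALSE), 3)
  expect_equal(sconet:::cpp_nbs_max_extent(s, 0.05, TRUE), 10.1)
})

test_that("identical group data produce an empty suprathreshold graph", {
  set.seed(55)
  block <- matrix(rnorm(8 * 6, 2.5, 0.2), 8, 6)
  vals <- rbind(block, block)
  d <- make_dataset(vals, rep(c("A", "B"), each = 8))
  res <- nbs_test(d, "A", "B", primary_threshold = 1, n_perm = 100,
                  seed = 1, covariates = character(0))
  expect_equal(length(res$components), 0L)
  expect_true(all(res$edge_stat == 0))
})

test_that("NBS localizes a planted decorrelated subnetwork", {
  spec <- cohort_spec(group_sizes = c(A = 19, B = 17), n_regions = 19,
                      modality = "subcortical_volume", latent_dim = 3,
                      seed = 56)
  d <- plant_effect(generate_cohort(spec), effect_spec("B", 1:8, 0.9))
  res <- nbs_test(d, "A", "B", n_perm = 200, seed = 2)
  expect_gt(length(res$components), 0)
  top <- res$components[[1]]
  planted <- atlas_regions("subcortical19")[1:8]
  expect_gte(length(intersect(top$nodes, planted)), 6)
  expect_lt(top$p_corrected, 0.05)
  expect_gte(min(vapply(res$components, `[[`, numeric(1), "p_corrected")),
             1 / 201)
  # every component is connected within the suprathreshold graph
  for (cmp in res$components) {
    sub <- res$edge_stat[cmp$nodes, cmp$nodes] > res$primary_threshold
    expect_true(r_connected(1L * sub))
  }
})

test_that("contrast report tabulates results and reprints identically", {
  d <- null_cohort(seed = 57)
  res <- permutation_test(d, "A", "B", metrics = "transitivity",
                          densities = c(0.2, 0.4), n_perm = 100, seed = 1)
  rep1 <- contrast_report(list(`A-B` = res))
  expect_equal(nrow(rep1$table), 2L)
  expect_null(rep1$nbs)
  expect_named(rep1$table, c("contrast", "metric", "density",
                             "observed_diff", "p", "q", "significant"))

  nbs <- nbs_test(d, "A", "B", primary_threshold = 1.5, n_perm = 100,
                  seed = 1)
  rep2 <- contrast_report(list(`A-B` = res), list(`A-B` = nbs))
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_contrast_report(rep2, f1)
  write_contrast_report(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(contrast_report(list()), "non-empty")
})
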