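test_that("cohort generation honours sizes, labels and determinism", {
  spec <- cohort_spec(seed = 11)
  d <- generate_cohort(spec)
  expect_equal(dim(d$values), c(48L, 68L))
  expect_equal(as.vector(table(d$group)[c("HC", "EM", "CM")]),
               c(19L, 17L, 12L))
  expect_identical(colnames(d$values), atlas_regions("desikan68"))
  expect_true(all(d$values > 0))
  expect_false(anyNA(d$values))
  expect_true(all(d$age >= 18))
  expect_true(all(d$sex %in% c(0L, 1L)))

  d2 <- generate_cohort(cohort_spec(seed = 11))
  expect_identical(d$values, d2$values)
  expect_identical(d$scores, d2$scores)
  d3 <- generate_cohort(cohort_spec(seed = 12))
  expect_false(identical(d$values, d3$values))

  em <- generate_cohort(cohort_spec(group_sizes = c(EM = 17), seed = 1))
  expect_equal(dim(em$values), c(17L, 68L))
})

test_that("score templates reproduce the cohort pattern of missingness", {
  d <- generate_cohort(cohort_spec(seed = 2))
  expect_true(all(is.na(d$scores$MIDAS[d$group == "HC"])))
  expect_true(all(is.na(d$scores$attacks[d$group == "HC"])))
  expect_false(anyNA(d$scores$MIDAS[d$group != "HC"]))
  expect_false(anyNA(d$scores$HADS_A))
  expect_true(all(d$scores$aura[d$group == "EM"] %in% 0:1))
  expect_true(all(d$scores$MIDAS[d$group != "HC"] >= 0))
})

test_that("sample correlations recover the loading-implied covariance", {
  spec <- cohort_spec(group_sizes = c(A = 500), latent_dim = 3,
                      noise_sd = 1e-6, age_slope = 0, sex_offset = 0,
                      seed = 5)
  d <- generate_cohort(spec)
  pop <- implied_correlation(spec)
  smp <- cor(d$values)
  expect_lt(max(abs(smp - pop)), 0.05)

  # rank-one noiseless factor model: loaded pairs correlate at 1
  spec1 <- cohort_spec(group_sizes = c(A = 400), latent_dim = 1,
                       noise_sd = 1e-8, age_slope = 0, sex_offset = 0,
                       n_regions = 6, seed = 5)
  d1 <- generate_cohort(spec1)
  expect_lt(max(abs(cor(d1$values) - 1)), 1e-6)
})

test_that("plant_effect is an identity at zero and touches only its cells", {
  d <- generate_cohort(cohort_spec(seed = 4))
  d0 <- plant_effect(d, effect_spec("EM", 1:6, decorrelation = 0,
                                    thickness_shift = 0))
  expect_equal(d0$values, d$values)

  d1 <- plant_effect(d, effect_spec("EM", 5:10, decorrelation = 0.5,
                                    thickness_shift = -0.1))
  changed <- d1$values != d$values
  expect_true(all(which(colSums(changed) > 0) %in% 5:10))
  expect_true(all(which(rowSums(changed) > 0) %in% which(d$group == "EM")))
})

test_that("full decorrelation removes within-target correlation at large n", {
  spec <- cohort_spec(group_sizes = c(A = 600), latent_dim = 3,
                      age_slope = 0, sex_offset = 0, seed = 6)
  d <- generate_cohort(spec)
  d <- plant_effect(d, effect_spec("A", 1:6, decorrelation = 1))
  r <- cor(d$values[, 1:6])
  expect_lt(mean(abs(r[upper.tri(r)])), 0.08)
})

test_that("a thickness shift moves the group column mean by that amount", {
  d <- generate_cohort(cohort_spec(seed = 7))
  d1 <- plant_effect(d, effect_spec("CM", 3, thickness_shift = -0.2))
  cm <- d$group == "CM"
  expect_equal(mean(d1$values[cm, 3]) - mean(d$values[cm, 3]), -0.2,
               tolerance = 1e-12)
  expect_equal(mean(d1$values[!cm, 3]), mean(d$values[!cm, 3]))
})

test_that("attach_scores produces exact affine copies at zero noise", {
  d <- generate_cohort(cohort_spec(seed = 8))
  feats <- matrix(rnorm(48 * 2), 48, 2,
                  dimnames = list(rownames(d$values), c("f1", "f2")))
  link <- score_link_spec("MIDAS", c(f1 = 1), intercept = 3, noise_sd = 0)
  d1 <- attach_scores(d, link, feats)
  expect_equal(d1$scores$MIDAS, unname(3 + feats[, "f1"]))
  # feature rows aligned by name even when shuffled
  d2 <- attach_scores(d, link, feats[sample(48), ])
  expect_equal(d2$scores$MIDAS, d1$scores$MIDAS)
})

test_that("generator and effect specs reject invalid parameters", {
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(base_sd = -1), "base_sd")
  expect_error(cohort_spec(group_sizes = c(A = 0)), "group sizes")
  expect_error(effect_spec("EM", 1:3, decorrelation = 1.2), "decorrelation")
  d <- generate_cohort(cohort_spec(seed = 1))
  expect_error(plant_effect(d, effect_spec("XX", 1:3)), "unknown group")
  expect_error(plant_effect(d, effect_spec("EM", c(1, 99))), "out of range")
  expect_error(plant_effect(d, effect_spec("EM", "not_a_region")),
               "not in atlas")
  expect_error(score_link_spec("MIDAS", c(f1 = 0)), "nonzero")
  feats <- matrix(0, 5, 1, dimnames = list(NULL, "f1"))
  expect_error(attach_scores(d, score_link_spec("MIDAS", c(f1 = 1)), feats),
               "5 rows")
})
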