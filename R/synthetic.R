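#' Specify a synthetic cohort
#'
#' Defines the generating model for a synthetic morphometry cohort: a
#' low-rank (latent factor) + diagonal covariance across regions, additive
#' age and sex confounds, and group sizes/demographics defaulting to the
#' three-group migraine template (HC = 19, EM = 17, CM = 12).
#'
#' The latent structure uses one global factor shared by all regions plus
#' `latent_dim - 1` block factors over a contiguous partition of the
#' regions, so the generated covariance has community structure — the
#' between-subject correlation phenomenon a structural covariance network
#' is built from. With the defaults, two regions in the same block
#' correlate at `base_sd^2 / (base_sd^2 + noise_sd^2)` (0.8) and regions
#' in different blocks at `global_share` times that (0.16), before
#' confounds.
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param modality `"cortical_thickness"` (mm) or `"subcortical_volume"`
#'   (mm^3); sets the default scales and the atlas label set when
#'   `n_regions` is 68 or 19.
#' @param n_regions Number of regions (68 cortical or 19 subcortical for
#'   the bundled atlases; other counts get synthetic labels).
#' @param base_mean Per-region baseline mean (scalar recycled).
#' @param base_sd Between-subject standard deviation of the structured
#'   (latent) component; must be > 0.
#' @param noise_sd Standard deviation of the unique (region-specific)
#'   noise; must be > 0.
#' @param latent_dim Number of latent factors (>= 1); factor 1 is global,
#'   the rest partition the regions into blocks.
#' @param block_sizes Optional integer vector of region counts per block
#'   (must sum to `n_regions`); overrides the equal partition and sets
#'   `latent_dim` to `length(block_sizes) + 1`. Use this to give the
#'   cohort a covariance module of a prescribed size (e.g. a 10-region
#'   module to disrupt with [plant_effect()]).
#' @param global_share Fraction of structured variance carried by the
#'   global factor (ignored when `latent_dim == 1`).
#' @param age_slope Change in the measure per year of age.
#' @param sex_offset Additive offset for male (sex coded F = 0, M = 1).
#' @param age_mean,age_sd Named per-group age distribution (years);
#'   Gaussian truncated at 18. Groups not named fall back to 33 +/- 10.
#' @param p_male Named per-group probability of male sex; fallback 0.4.
#' @param seed Master seed (mandatory); split hierarchically per group and
#'   per score so adding a score does not perturb the morphometry draws.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(group_sizes = c(HC = 19, EM = 17, CM = 12),
                        modality = c("cortical_thickness",
                                     "subcortical_volume"),
                        n_regions = NULL,
                        base_mean = NULL,
                        base_sd = NULL,
                        noise_sd = NULL,
                        latent_dim = 5,
                        block_sizes = NULL,
                        global_share = 0.2,
                        age_slope = NULL,
                        sex_offset = NULL,
                        age_mean = c(HC = 31.7, EM = 32.7, CM = 38.19),
                        age_sd = c(HC = 9.2, EM = 9.9, CM = 16.15),
                        p_male = c(HC = 9 / 19, EM = 4 / 17, CM = 4 / 12),
                        seed = 1L) {
  modality <- match.arg(modality)
  cortical <- modality == "cortical_thickness"
  if (is.null(n_regions)) n_regions <- if (cortical) 68L else 19L
  if (is.null(base_mean)) base_mean <- if (cortical) 2.5 else 4000
  if (is.null(base_sd)) base_sd <- if (cortical) 0.14 else 450
  if (is.null(noise_sd)) noise_sd <- if (cortical) 0.07 else 225
  if (is.null(age_slope)) age_slope <- if (cortical) -0.005 else -12
  if (is.null(sex_offset)) sex_offset <- if (cortical) -0.02 else 250

  if (is.null(names(group_sizes)) || anyDuplicated(names(group_sizes)))
    stopf("group_sizes must have unique names")
  if (any(group_sizes < 1) || any(group_sizes != floor(group_sizes)))
    stopf("all group sizes must be integers >= 1")
  if (!is_count(n_regions)) stopf("n_regions must be a count >= 1")
  if (!all(is.finite(base_sd)) || any(base_sd <= 0))
    stopf("base_sd must be > 0")
  if (!all(is.finite(noise_sd)) || any(noise_sd <= 0))
    stopf("noise_sd must be > 0")
  if (!is.null(block_sizes)) {
    if (sum(block_sizes) != n_regions)
      stopf("block_sizes must sum to n_regions (%d)", n_regions)
    if (any(block_sizes < 1)) stopf("block sizes must be >= 1")
    latent_dim <- length(block_sizes) + 1L
  }
  if (!is_count(latent_dim)) stopf("latent_dim must be a count >= 1")
  if (latent_dim > n_regions)
    stopf("latent_dim (%d) exceeds n_regions (%d)", latent_dim, n_regions)
  if (global_share < 0 || global_share > 1)
    stopf("global_share must lie in [0, 1]")
  if (!is_count(abs(seed) + 1)) stopf("seed must be a single integer")

  base_mean <- rep_len(base_mean, n_regions)

  spec <- list(group_sizes = group_sizes, modality = modality,
               n_regions = as.integer(n_regions), base_mean = base_mean,
               base_sd = base_sd, noise_sd = noise_sd,
               latent_dim = as.integer(latent_dim),
               block_sizes = block_sizes,
               global_share = global_share, age_slope = age_slope,
               sex_offset = sex_offset, age_mean = age_mean,
               age_sd = age_sd, p_male = p_male, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# Loading matrix implied by a cohort_spec: n_regions x latent_dim.
spec_loadings <- function(spec) {
  n <- spec$n_regions
  L <- matrix(0, n, spec$latent_dim)
  if (spec$latent_dim == 1L) {
    L[, 1] <- spec$base_sd
  } else {
    L[, 1] <- sqrt(spec$global_share) * spec$base_sd
    n_blocks <- spec$latent_dim - 1L
    block <- if (!is.null(spec$block_sizes))
               rep(seq_along(spec$block_sizes), spec$block_sizes)
             else if (n_blocks == 1L) rep(1L, n)
             else cut(seq_len(n), breaks = n_blocks, labels = FALSE)
    for (i in seq_len(n))
      L[i, 1L + block[i]] <- sqrt(1 - spec$global_share) * spec$base_sd
  }
  L
}

#' Population region-by-region correlation implied by a cohort spec
#'
#' The correlation induced by the latent loadings and unique noise alone
#' (age/sex confounds excluded — they are removed by residualization
#' downstream).
#'
#' @param spec A [cohort_spec()].
#' @return `n_regions` x `n_regions` correlation matrix.
#' @export
implied_correlation <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  L <- spec_loadings(spec)
  S <- L %*% t(L)
  diag(S) <- diag(S) + spec$noise_sd^2
  stats::cov2cor(S)
}

group_demog <- function(spec, g, n) {
  am <- if (g %in% names(spec$age_mean)) spec$age_mean[[g]] else 33
  asd <- if (g %in% names(spec$age_sd)) spec$age_sd[[g]] else 10
  pm <- if (g %in% names(spec$p_male)) spec$p_male[[g]] else 0.4
  list(age = rnorm_trunc(n, am, asd, lower = 18),
       sex = as.integer(runif(n) < pm))
}

# Group-specific clinical score templates (MIDAS in days, attacks in
# headache days/month, HADS on the 0-21 scale, sleep in hours, aura 0/1).
# Scores undefined for a group (controls have no MIDAS/attacks/aura) are NA.
score_template_draw <- function(score, group, n) {
  draw <- function(m, s, lower = 0) pmax(rnorm(n, m, s), lower)
  switch(score,
    MIDAS = switch(group, EM = draw(19.65, 20.61), CM = draw(55.50, 12.76),
                   rep(NA_real_, n)),
    attacks = switch(group, EM = draw(4.0, 3.8), CM = draw(18.50, 4.25),
                     rep(NA_real_, n)),
    HADS_A = switch(group, HC = draw(3.4, 2.3), EM = draw(5.3, 3.9),
                    CM = draw(5.0, 3.46), rep(NA_real_, n)),
    HADS_D = switch(group, HC = draw(1.3, 1.2), EM = draw(3.4, 2.6),
                    CM = draw(4.67, 2.96), rep(NA_real_, n)),
    sleep = draw(7.2, 0.9, lower = 3),
    aura = switch(group, EM = as.numeric(runif(n) < 12 / 17),
                  CM = as.numeric(runif(n) < 5 / 12), rep(NA_real_, n)),
    rep(NA_real_, n))
}

score_names <- function() c("MIDAS", "attacks", "HADS_A", "HADS_D",
                            "sleep", "aura")

#' Generate a synthetic morphometry cohort
#'
#' Draws a subjects-by-regions matrix from the latent-factor model of a
#' [cohort_spec()]: `base_mean + loadings %*% factors + age_slope * (age -
#' mean age) + sex_offset * sex + noise`. Clinical scores are drawn from
#' group templates (controls get `NA` for patient-only scores); use
#' [attach_scores()] to link scores to features instead.
#'
#' @param spec A [cohort_spec()].
#' @return A `morph_dataset`: values matrix (subjects x regions, labelled),
#'   group factor, age, sex, a scores data frame, and the generator state
#'   needed by [plant_effect()].
#' @examples
#' d <- generate_cohort(cohort_spec(seed = 1))
#' dim(d$values)  # 48 x 68
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$group_sizes)
  n_total <- sum(spec$group_sizes)
  p <- spec$n_regions
  L <- spec_loadings(spec)

  group_vec <- character(0)
  ids <- character(0)
  age <- numeric(0)
  sex <- integer(0)
  Fm <- matrix(0, 0, spec$latent_dim)
  Em <- matrix(0, 0, p)
  for (g in groups) {
    n_g <- spec$group_sizes[[g]]
    out <- with_seed(split_seed(spec$seed, paste0("morph:", g)), {
      demog <- group_demog(spec, g, n_g)
      list(demog = demog,
           f = matrix(rnorm(n_g * spec$latent_dim), n_g, spec$latent_dim),
           e = matrix(rnorm(n_g * p), n_g, p))
    })
    group_vec <- c(group_vec, rep(g, n_g))
    ids <- c(ids, paste0(g, sprintf("%02d", seq_len(n_g))))
    age <- c(age, out$demog$age)
    sex <- c(sex, out$demog$sex)
    Fm <- rbind(Fm, out$f)
    Em <- rbind(Em, out$e)
  }

  regions <- if (!is.na(atlas_for_n(p))) atlas_regions(atlas_for_n(p))
             else sprintf("region%03d", seq_len(p))
  base <- matrix(rep(spec$base_mean, each = n_total), n_total, p) +
    spec$age_slope * (age - mean(age)) + spec$sex_offset * sex
  values <- base + Fm %*% t(L) + spec$noise_sd * Em
  dimnames(values) <- list(ids, regions)

  scores <- data.frame(row.names = ids)
  for (s in score_names()) {
    col <- numeric(0)
    for (g in groups) {
      n_g <- spec$group_sizes[[g]]
      col <- c(col, with_seed(split_seed(spec$seed,
                                         paste0("score:", s, ":", g)),
                              score_template_draw(s, g, n_g)))
    }
    scores[[s]] <- col
  }

  if (spec$modality == "cortical_thickness" && any(values <= 0))
    stopf("generated thickness values are not all positive; check spec scales")

  structure(list(values = values, regions = regions,
                 modality = spec$modality,
                 group = factor(group_vec, levels = groups),
                 age = age, sex = sex, scores = scores,
                 residualized = FALSE,
                 generator = list(spec = spec, loadings = L, factors = Fm,
                                  noise = Em, base = base,
                                  effects = list())),
            class = "morph_dataset")
}

#' @export
print.morph_dataset <- function(x, ...) {
  cat(sprintf("<morph_dataset> %d subjects x %d regions (%s)%s\n",
              nrow(x$values), ncol(x$values), x$modality,
              if (isTRUE(x$residualized)) ", residualized" else ""))
  cat("  groups:", paste(sprintf("%s=%d", levels(x$group),
                                 tabulate(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Specify a planted covariance effect
#'
#' @param target_group Group label receiving the effect.
#' @param target_regions Region indices or labels forming the planted
#'   subnetwork.
#' @param decorrelation Fraction in `[0, 1]` by which the latent loadings
#'   of the target regions are attenuated in the target group (1 removes
#'   their shared covariance entirely).
#' @param thickness_shift Additive mean shift (measure units) applied to
#'   the target cells.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(target_group, target_regions, decorrelation = 0,
                        thickness_shift = 0) {
  if (!is_scalar_num(decorrelation) || decorrelation < 0 ||
      decorrelation > 1)
    stopf("decorrelation must lie in [0, 1]")
  if (!is_scalar_num(thickness_shift))
    stopf("thickness_shift must be a single number")
  structure(list(target_group = target_group,
                 target_regions = target_regions,
                 decorrelation = decorrelation,
                 thickness_shift = thickness_shift),
            class = "effect_spec")
}

#' Plant a subnetwork-specific covariance disruption
#'
#' Rebuilds the target cells (target group x target regions) from the
#' stored generator state with the latent loadings attenuated by
#' `decorrelation` and the mean shifted by `thickness_shift`; all other
#' cells are untouched. Provides ground truth for power and localization
#' tests of the permutation and network-based-statistic machinery.
#'
#' @param data A generated `morph_dataset` (must carry generator state).
#' @param effect An [effect_spec()].
#' @return The modified `morph_dataset`.
#' @export
plant_effect <- function(data, effect) {
  stopifnot(inherits(data, "morph_dataset"), inherits(effect, "effect_spec"))
  if (is.null(data$generator))
    stopf("plant_effect needs a generated dataset (generator state present)")
  if (!effect$target_group %in% levels(data$group))
    stopf("unknown group '%s'", effect$target_group)
  tr <- effect$target_regions
  if (is.character(tr)) {
    bad <- setdiff(tr, data$regions)
    if (length(bad))
      stopf("regions not in atlas: %s", paste(bad, collapse = ", "))
    cols <- match(tr, data$regions)
  } else {
    if (any(tr < 1 | tr > length(data$regions)))
      stopf("region index out of range 1..%d", length(data$regions))
    cols <- as.integer(tr)
  }
  rows <- which(data$group == effect$target_group)
  g <- data$generator
  spec <- g$spec
  structured <- g$factors[rows, , drop = FALSE] %*%
    t(g$loadings[cols, , drop = FALSE])
  data$values[rows, cols] <- g$base[rows, cols] +
    (1 - effect$decorrelation) * structured +
    spec$noise_sd * g$noise[rows, cols] +
    effect$thickness_shift
  data$generator$effects <- c(g$effects, list(effect))
  data
}

#' Specify a feature-linked clinical score
#'
#' @param score Score name (e.g. `"MIDAS"`, `"attacks"`, `"HADS_A"`,
#'   `"HADS_D"`, `"aura"`, `"sleep"`).
#' @param weights Named numeric vector: weight per feature column; at
#'   least one weight must be nonzero.
#' @param intercept Intercept added to the linear combination.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (>= 0).
#' @return A `score_link_spec` object.
#' @export
score_link_spec <- function(score, weights, intercept = 0, noise_sd = 0) {
  if (is.null(names(weights)) || !is.numeric(weights))
    stopf("weights must be a named numeric vector")
  if (all(weights == 0)) stopf("a linked score needs a nonzero weight")
  if (!is_scalar_num(noise_sd) || noise_sd < 0)
    stopf("noise_sd must be >= 0")
  structure(list(score = score, weights = weights, intercept = intercept,
                 noise_sd = noise_sd), class = "score_link_spec")
}

#' Attach feature-linked scores to a dataset
#'
#' Overwrites each linked score with `intercept + sum(weight * feature) +
#' noise`, providing known ground truth for the prediction module.
#' Scores not named in `links` keep their template draws (independent of
#' the features).
#'
#' @param data A `morph_dataset`.
#' @param links List of [score_link_spec()] objects.
#' @param subject_features Numeric matrix, one row per subject of `data`
#'   (aligned by rownames when present) with named columns covering every
#'   weight name.
#' @param seed Master seed for the noise draws; defaults to the
#'   generator's seed when available.
#' @return The `morph_dataset` with updated scores.
#' @export
attach_scores <- function(data, links, subject_features,
                          seed = NULL) {
  stopifnot(inherits(data, "morph_dataset"))
  if (inherits(links, "score_link_spec")) links <- list(links)
  n <- nrow(data$values)
  if (nrow(subject_features) != n)
    stopf("subject_features has %d rows but the dataset has %d subjects",
          nrow(subject_features), n)
  if (!is.null(rownames(subject_features)) &&
      !identical(rownames(subject_features), rownames(data$values))) {
    if (!setequal(rownames(subject_features), rownames(data$values)))
      stopf("subject_features rownames do not match the dataset subjects")
    subject_features <-
      subject_features[rownames(data$values), , drop = FALSE]
  }
  if (is.null(seed)) {
    seed <- if (!is.null(data$generator)) data$generator$spec$seed else 1L
  }
  for (link in links) {
    stopifnot(inherits(link, "score_link_spec"))
    missing_f <- setdiff(names(link$weights), colnames(subject_features))
    if (length(missing_f))
      stopf("features absent from subject_features: %s",
            paste(missing_f, collapse = ", "))
    lin <- as.numeric(subject_features[, names(link$weights),
                                       drop = FALSE] %*% link$weights)
    noise <- with_seed(split_seed(seed, paste0("linkscore:", link$score)),
                       rnorm(n, 0, link$noise_sd))
    data$scores[[link$score]] <- link$intercept + lin + noise
  }
  data
}
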