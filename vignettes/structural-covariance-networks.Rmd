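---
title: "Structural covariance networks: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

A structural covariance network (SCN) treats atlas regions as nodes and
the *between-subject* Pearson correlation of a regional morphometric
measure — cortical thickness (mm) over the 68 Desikan regions, or
subcortical volume (mm³) over 9 structures per hemisphere plus the brain
stem — as edge weights, computed within a group. Because a group yields
one network rather than one network per subject, group comparison needs
resampling: `sconet` residualizes age and sex within group, correlates,
binarizes each group's matrix at a sweep of edge densities under a
connectedness constraint, computes graph measures (Louvain modularity,
transitivity, degree assortativity, mean clustering, mean node and edge
betweenness), and tests group differences by reassigning subjects to
pseudo-groups and rebuilding the entire pipeline in every permutation.
Edge-level localization uses the network-based statistic (NBS), and
clinical severity scores are predicted from jackknife network features
with cross-validated support vector regression (SVR).

## The synthetic cohort model

Patient morphometry of this kind is rarely shareable, so the package
ships a generator whose output has the statistical structure the
analysis assumes, making every downstream stage testable:

\[ y_{sr} = \mu_r + \lambda_r^\top f_s + \beta_{\text{age}}(a_s - \bar a)
   + \beta_{\text{sex}} x_s + \varepsilon_{sr} \]

* one **global latent factor** shared by all regions plus block factors
  over a partition of the regions, giving the covariance its community
  structure (`latent_dim`, or explicit `block_sizes`);
* Gaussian unique noise; age drawn from group-specific truncated
  normals (lower bound 18 y), sex from group-specific Bernoulli draws;
* group sizes, age and sex distributions, and clinical score templates
  (MIDAS, attacks/month, HADS-A/D, aura prevalence) default to the
  three-group migraine cohort shape: HC = 19, EM = 17, CM = 12.

Default calibration (chosen once, with units): baseline thickness
2.5 mm, structured between-subject SD `base_sd` = 0.14 mm, unique noise
`noise_sd` = 0.07 mm, `global_share` = 0.2. These imply within-module
correlations of about 0.8 and between-module correlations of about
0.16 — the strong within-lobe covariance and weak long-range covariance
typical of published cortical-thickness SCN matrices. No empirical
covariance magnitudes are available for the motivating cohort, so these
are modelling choices, not estimates. Subcortical defaults scale the
same shares to mm³ (4000 / 450 / 225).

Seeding is hierarchical: one master seed is split per group and per
score, so attaching or changing a clinical score never perturbs the
morphometry draws.

`plant_effect()` creates ground truth: inside one group it attenuates
the latent loadings of a target region set by a `decorrelation` factor
and/or shifts its mean. Because it rebuilds only the targeted cells from
the stored factor scores, every other cell is bit-identical to the
unperturbed cohort. `attach_scores()` overwrites a clinical score with a
known linear function of supplied per-subject features plus noise —
the ground truth for SVR recovery tests.

What the generator does **not** emulate: spatial autocorrelation on the
cortical surface, segmentation error, heavy-tailed or site-dependent
measurement noise, and hemispheric asymmetries. Passing tests therefore
demonstrate correctness of the machinery under a faithful covariance
model, not robustness to all real-data pathologies.

## Network construction

* **Residualization.** OLS residuals on `[1, age, sex]`, computed
  within each group so group mean differences cannot leak into the
  covariance. Inside every permutation the residualization is redone on
  the pseudo-groups, so the null reflects the full observed pipeline.
* **Thresholding.** At density *d* the network keeps
  `round(d·n(n−1)/2)` edges: first the maximum spanning tree of the
  correlation weights (guaranteeing one connected component), then
  remaining edges by decreasing correlation. Ties break by
  lexicographic node-pair order, so results are bit-reproducible.
  Networks across a sweep are nested by construction.
* **Edge candidacy.** With the default `"positive"` ranking, negative
  correlations are never added beyond the spanning backbone (the SCN
  literature treats negative covariance as non-edges); `"absolute"`
  ranks by |r|. With small samples the positive-candidate count
  fluctuates strongly across permutation draws (edge correlations share
  subjects and factors), and a requested density can become
  unconstructible mid-permutation; the package treats that as an error
  rather than silently changing the edge count. The simulation studies
  in the test suite therefore use `"absolute"` ranking, under which
  every density is constructible for every draw; permutation validity
  is unaffected because observed and permuted data pass through the
  identical pipeline.
* **Default grid** 0.10–0.50 in steps of 0.05 (nine densities),
  spanning the fragmentation-prone to near-random regimes; the minimal
  connected density is 2/n (≈ 0.105 for 19 nodes — subcortical grids
  start at 0.15).

## Graph measures

The five measures are implemented in compiled code with exact
small-graph oracles in the test suite (brute-force triangle/triplet
counts, explicit shortest-path enumeration, exhaustive partition search
up to n = 8) and an independent cross-check against igraph:

* transitivity `3·triangles / triplets`; mean clustering coefficient
  (`2t_i / k_i(k_i−1)`, 0 for degree < 2);
* degree assortativity as the Pearson correlation over the 2m ordered
  edge endpoints — undefined (flagged, `NA`) on regular graphs;
* node betweenness by Brandes accumulation, endpoints excluded,
  normalized by `(n−1)(n−2)/2`; edge betweenness normalized by
  `n(n−1)/2`; summaries are means over nodes / present edges;
* Louvain modularity with a seeded random sweep order, best of
  `n_restarts = 20` restarts (Louvain is order-dependent; the
  permutation engine needs reproducibility). Alternate restarts begin
  from random initial partitions rather than singletons, and every
  restart ends with a deterministic single-node refinement pass on the
  original graph — the greedy merge order from singletons cannot reach
  every optimum on small or weakly modular graphs, and both additions
  can only raise Q. Q is always recomputed from the returned partition
  with the Newman formula.

## Group inference

The permutation test reassigns the pooled subjects of the two groups to
pseudo-groups of the original sizes (5000 iterations by default),
reruns residualization → correlation → thresholding → metric, and takes
the two-tailed percentile position with the add-one rule
`p = (1 + #{|null| ≥ |obs|}) / (n_perm + 1)`, so p can never be 0.
FDR correction is Benjamini–Hochberg across the densities of one metric
(the correction family is not recoverable from the motivating study's
description; a wider metrics-by-densities family is a one-line change
on the returned p matrix). Group order only flips the sign of the
reported difference: permutations are generated in a canonical group
order, so `p` is exactly invariant under swapping the contrast.

NBS computes per-edge statistics on the *unthresholded* residualized
correlation matrices — binarized edges carry no within-group variance —
using the Fisher-z difference
`|atanh r_A − atanh r_B| / sqrt(1/(n_A−3) + 1/(n_B−3))` (a raw
`|r_A − r_B|` option is provided), links edges above the primary
threshold (default 2.58, the two-tailed 0.01 z point; NBS is
threshold-dependent by construction) into connected components, and
compares each component's extent (edge count; intensity optional)
against the permutation null of the maximal component. Correlations are
clipped to |r| ≤ 1 − 1e−7 before `atanh`. Note that the nominal unit
variance of the z difference ignores the two residualized covariates,
so the edge statistic runs slightly hot under the null; the permutation
null absorbs this (family-wise error remains controlled), but observed
components are compared against a correspondingly heavier null.

## Prediction

Group-level networks give no per-subject features, and the motivating
analysis does not say how per-patient prediction was performed — the
jackknife construction here is this package's explicit interpretation.
For subject *s* in a group of size *n*, each metric-at-density becomes
the pseudovalue `n·M_full − (n−1)·M_−s`, where `M_−s` reruns the whole
group pipeline without *s*. One caution, measured in development and
worth stating plainly: for threshold-binarized network metrics the
leave-one-out shift does not shrink at the 1/n rate that makes
jackknife pseudovalues unbiased for smooth statistics, so pseudovalue
*means* can sit far from the group-level metric. They are used here as
subject-influence features for prediction — a role for which only their
between-subject variation matters — not as estimators.

SVR (epsilon regression, linear kernel by default — small n, many
features) is evaluated by k-fold cross-validation repeated
`n_repetitions = 10` times with seeded fold shuffles; standardization
parameters come from the training folds only. Each repetition's
"regression coefficient" is the Pearson correlation between pooled
held-out predictions and observed scores (point-biserial for the binary
aura flag), and a prediction is called *robust* when the median
coefficient strictly exceeds 0.5. "Ten times" is read as ten
repetitions of 10-fold CV (one coefficient per repetition), matching a
per-validation scatter of coefficients.

## Calibration and power: what the simulations show

The acceptance suite (and `scripts/acceptance.R`) recomputes:

* **Type-I error.** Two pseudo-groups of 19 and 17 subjects from one
  generating spec, 19-region atlas, densities 0.15–0.50, 500
  permutations, 200 replicates: the permutation p at the middle density
  rejects at α = 0.05 between 3% and 8% per metric and passes a
  Kolmogorov–Smirnov uniformity check at α = 0.01. The 19-region atlas
  and these replicate counts were chosen to keep the study inside
  minutes of CPU; calibration is a property of the machinery, not of
  the atlas size.
* **Power and localization.** Cohorts with a dedicated 10-region
  covariance module (blocks 10/19/19/20), fully decorrelated
  (`decorrelation = 0.9`) in the 17-subject group, 50 replicates. NBS
  localization (≥ 6 of the 10 planted regions in the top component)
  succeeds in well over 80% of replicates. The modularity permutation
  test does **not** reach 80% detection under these conditions: the
  population modularity shift induced by deleting one of four modules
  is ≈ 0.12 (computed from the model correlation matrices), while the
  sampling spread of a modularity difference between groups of 19 and
  17 subjects is of the same order, an effect-size limit rather than an
  implementation artefact. Detection rates are reported as computed;
  localization, not global modularity, is the sensitive instrument at
  these sample sizes.
* **SVR.** With MIDAS linked to assortativity pseudovalues at 2:1
  signal-to-noise (SD ratio) in the 29 patients, the median
  cross-validated coefficient clears the 0.5 robustness line; with an
  unlinked, group-structure-free score (sleep hours) it crosses 0.5 in
  fewer than 5% of 100 cohorts. Scores with strong group structure
  (e.g. MIDAS templates: CM ≫ EM) can correlate with features through
  group membership alone; null calibration therefore uses a score whose
  distribution is common to all subjects.

## Numerical and degenerate-input conventions

* Correlation requires ≥ 4 subjects per group and errors on
  zero-variance regions, naming them.
* An undefined assortativity at some density is recorded as `NA` and
  dropped from that metric's FDR family with a message.
* `round()` follows R's round-half-even convention everywhere an edge
  count is derived from a density.
* All randomness flows from explicit integer seeds (R draws for subject
  reassignment and fold shuffles; a dedicated Mersenne Twister stream
  inside compiled Louvain), so every result in a run is reproducible
  from the run configuration alone, and pipeline reruns are
  byte-identical.
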