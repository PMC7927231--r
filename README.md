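# sconet — structural covariance network analysis of brain morphometry

`sconet` is an R toolkit for group-level **structural covariance
networks** (SCNs): graphs whose nodes are atlas regions and whose edges
are between-subject correlations of a regional morphometric measure —
cortical thickness over the 68-region Desikan parcellation, or
subcortical volumes over 19 structures. It was built for the kind of
clinical neuroimaging study that compares small patient groups (e.g.
episodic vs chronic migraine vs controls) and asks three questions:

1. **Do global network properties differ between groups?**
   Covariate residualization → per-group correlation matrices →
   density-swept, connectedness-preserving binarization → graph metrics
   (Louvain modularity *Q*, transitivity, degree assortativity, mean
   clustering, node/edge betweenness) → subject-reassignment
   permutation tests with Benjamini–Hochberg FDR across densities:
   `p(d) = (1 + #{|null| ≥ |obs|}) / (n_perm + 1)`.
2. **Where in the connectome?** The network-based statistic (NBS):
   Fisher-z edge statistics `|z_A − z_B| / sqrt(1/(n_A−3) + 1/(n_B−3))`,
   suprathreshold components, family-wise corrected by the permutation
   null of the maximal component extent.
3. **Do network measures carry clinical information?** Jackknife
   pseudovalue features (`n·M_full − (n−1)·M_−s`) feed an epsilon-SVR
   with repeated 10-fold cross-validation; a score is predicted
   "robustly" when the median cross-validated correlation between
   predicted and observed exceeds 0.5.

Because patient MRI tables of this kind are rarely public, the package
includes a first-class synthetic-cohort generator (latent-factor
covariance with plantable subnetwork disruptions and feature-linked
clinical scores) so the entire pipeline is testable end to end.

The graph kernel (thresholding, metrics, seeded restartable Louvain,
Brandes betweenness, NBS components) is implemented in C++ via Rcpp and
is validated against brute-force oracles and igraph in the test suite.

## Worked example

```r
library(sconet)

# a synthetic three-group cohort shaped like a migraine study
# (HC = 19, EM = 17, CM = 12; 68 Desikan regions), with a planted
# 10-region covariance module fully decorrelated in the episodic group
spec <- cohort_spec(block_sizes = c(10, 19, 19, 20), seed = 42)
d    <- plant_effect(generate_cohort(spec), effect_spec("EM", 1:10, 0.9))

res <- permutation_test(d, "EM", "HC",
                        metrics = c("modularity", "transitivity",
                                    "assortativity"),
                        n_perm = 500, seed = 1, ranking = "absolute")
print(res)
#> <difference_result> EM - HC (n = 17 vs 19), 500 permutations
#>   modularity        min q = 0.00898 significant densities: 3/9
#>   transitivity      min q = 0.77    significant densities: 0/9
#>   assortativity     min q = 0.0539  significant densities: 0/9

nb <- nbs_test(d, "EM", "HC", n_perm = 500, seed = 1)
print(nb)
#> <nbs_result> EM vs HC, threshold 2.58 (fisher_z), 500 permutations
#>   component 1: 21 nodes, 36 edges, p = 0.3513
#>   component 2: 2 nodes, 1 edges, p = 1.0000
length(intersect(nb$components[[1]]$nodes, atlas_regions("desikan68")[1:10]))
#> [1] 10
```

Reading the printout: the planted module loss shifts modularity enough
to survive FDR at three of nine densities (min q = 0.009), while
transitivity shows nothing — the effect is module-specific, not a
global closure change. The NBS top component contains all ten planted
regions (exact localization); its family-wise p (0.35) illustrates how
heavy the max-component permutation null is at these sample sizes —
with 36 subjects, component membership is more informative than
component significance.

A complete run (tables in, report out) is driven by a YAML config:

```r
cfg <- read_run_config(system.file("extdata", "demo-config.yaml",
                                   package = "sconet"))
run_pipeline(cfg, "runs/demo")
```

or from a shell via `inst/scripts/run-pipeline.R`. Real data enter as
FreeSurfer-style tab-separated tables (`aparcstats2table` /
`asegstats2table` dialect) through `read_morphometry_table()` and
`read_metadata()`.

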