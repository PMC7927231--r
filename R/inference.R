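perm_pvalue <- function(observed, null) {
  null <- null[!is.na(null)]
  (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted values (monotone-enforced,
#' capped at 1), as used across the densities of one metric.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Adjusted q-values, same length.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p)) stopf("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Permutation test of group differences in network metrics
#'
#' Runs the full observed pipeline — within-group residualization on the
#' covariates, inter-regional Pearson correlation, connectedness-
#' preserving density thresholding, metric evaluation — on the true
#' labels, then rebuilds it under `n_perm` random reassignments of the
#' pooled subjects to pseudo-groups of the original sizes (the
#' residualization is redone inside every iteration so the null reflects
#' the whole pipeline). Two-tailed p per density from the percentile
#' position with the add-one rule, `p = (1 + #{|null| >= |obs|}) /
#' (n_perm + 1)`; q by Benjamini-Hochberg across densities within each
#' metric.
#'
#' @param data A `morph_dataset` (raw; residualization happens inside).
#' @param group_a,group_b Group labels; the reported difference is
#'   `group_a - group_b`.
#' @param metrics Subset of [metric_names()].
#' @param densities Density grid (see [default_densities()]).
#' @param covariates Covariates residualized within each (pseudo-)group.
#' @param n_perm Number of permutations (study default 5000; >= 100).
#' @param seed Master seed (label shuffles and Louvain restarts).
#' @param n_restarts Louvain restarts per network.
#' @param ranking Edge ranking, see [threshold_at_density()].
#' @return A `difference_result` with `observed`, `null`, `p`, `q`
#'   (densities x metrics), and the call settings.
#' @export
permutation_test <- function(data, group_a, group_b,
                             metrics = c("modularity", "transitivity",
                                         "assortativity", "clustering",
                                         "node_betweenness",
                                         "edge_betweenness"),
                             densities = default_densities(),
                             covariates = c("age", "sex"),
                             n_perm = 5000, seed = 1, n_restarts = 20,
                             ranking = c("positive", "absolute")) {
  stopifnot(inherits(data, "morph_dataset"))
  ranking <- match.arg(ranking)
  if (n_perm < 100) stopf("n_perm must be >= 100 (study default 5000)")
  for (g in c(group_a, group_b))
    if (!g %in% levels(data$group)) stopf("unknown group '%s'", g)
  rows_a <- which(data$group == group_a)
  rows_b <- which(data$group == group_b)
  if (length(rows_a) < 4L || length(rows_b) < 4L)
    stopf("both groups need at least 4 subjects (have %d and %d)",
          length(rows_a), length(rows_b))

  want <- metric_want(metrics)
  n <- ncol(data$values)
  check_densities(n, densities)
  edge_counts <- vapply(densities, edge_count_for_density, integer(1), n = n)
  covmat <- if (length(covariates)) make_covmat(data, covariates) else NULL

  # canonical orientation so that swapping group_a/group_b only flips the
  # sign of the difference and leaves the permutation null (and p) intact
  canon <- sort(c(group_a, group_b))
  sign_user <- if (identical(group_a, canon[1])) 1 else -1
  rows1 <- which(data$group == canon[1])
  rows2 <- which(data$group == canon[2])
  pooled <- c(rows1, rows2)
  n1 <- length(rows1)

  base_seed <- split_seed(seed, "louvain")
  eval_diff <- function(r1, r2, perm_idx) {
    m1 <- group_sweep_metrics(data$values, r1, covmat, edge_counts, want,
                              ranking == "absolute", n_restarts,
                              (base_seed + 2L * perm_idx) %% 2147483647L)
    m2 <- group_sweep_metrics(data$values, r2, covmat, edge_counts, want,
                              ranking == "absolute", n_restarts,
                              (base_seed + 2L * perm_idx + 1L) %% 2147483647L)
    m1 - m2
  }

  observed_c <- eval_diff(rows1, rows2, 0L)
  D <- length(densities)
  M <- length(metric_names())
  null_c <- array(NA_real_, c(n_perm, D, M))
  with_seed(split_seed(seed, "permtest"), {
    for (b in seq_len(n_perm)) {
      shuffled <- sample(pooled)
      null_c[b, , ] <- eval_diff(shuffled[seq_len(n1)],
                                 shuffled[-seq_len(n1)], b)
    }
  })

  sel <- which(want)
  p <- matrix(NA_real_, D, length(sel),
              dimnames = list(format(densities), metric_names()[sel]))
  for (j in seq_along(sel)) {
    for (d in seq_len(D)) {
      if (is.na(observed_c[d, sel[j]])) next
      p[d, j] <- perm_pvalue(observed_c[d, sel[j]], null_c[, d, sel[j]])
    }
    if (anyNA(p[, j]))
      msg("metric '%s': %d density level(s) undefined, dropped from FDR",
          metric_names()[sel[j]], sum(is.na(p[, j])))
  }
  q <- apply(p, 2, fdr_adjust)
  if (is.null(dim(q))) q <- matrix(q, nrow = D, dimnames = dimnames(p))

  observed <- sign_user * observed_c[, sel, drop = FALSE]
  dimnames(observed) <- dimnames(p)
  null_u <- sign_user * null_c[, , sel, drop = FALSE]

  structure(list(metrics = metric_names()[sel], densities = densities,
                 observed = observed, null = null_u, p = p, q = q,
                 group_a = group_a, group_b = group_b,
                 n_a = length(rows_a), n_b = length(rows_b),
                 n_perm = n_perm, seed = seed, covariates = covariates),
            class = "difference_result")
}

#' @export
print.difference_result <- function(x, ...) {
  cat(sprintf("<difference_result> %s - %s (n = %d vs %d), %d permutations\n",
              x$group_a, x$group_b, x$n_a, x$n_b, x$n_perm))
  for (m in x$metrics) {
    sig <- sum(x$q[, m] < 0.05, na.rm = TRUE)
    cat(sprintf("  %-17s min q = %-7s significant densities: %d/%d\n", m,
                format(suppressWarnings(min(x$q[, m], na.rm = TRUE)),
                       digits = 3),
                sig, length(x$densities)))
  }
  invisible(x)
}

#' Plot observed metric differences against the permutation null
#'
#' One panel per metric: observed group difference across densities with
#' the central 95% band of the permutation null.
#'
#' @param x A `difference_result`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.difference_result <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$metrics)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in seq_along(x$metrics)) {
    m <- x$metrics[j]
    nu <- x$null[, , j]
    lo <- apply(nu, 2, quantile, 0.025, na.rm = TRUE)
    hi <- apply(nu, 2, quantile, 0.975, na.rm = TRUE)
    ylim <- range(c(lo, hi, x$observed[, m]), na.rm = TRUE)
    graphics::plot(x$densities, x$observed[, m], type = "b", pch = 16,
                   ylim = ylim, xlab = "density", ylab = "difference",
                   main = m, ...)
    graphics::lines(x$densities, lo, lty = 2, col = "grey40")
    graphics::lines(x$densities, hi, lty = 2, col = "grey40")
    graphics::abline(h = 0, col = "grey70")
    sig <- which(x$q[, m] < 0.05)
    if (length(sig))
      graphics::points(x$densities[sig], x$observed[sig, m], pch = 8,
                       col = "red3")
  }
  invisible(x)
}

fisher_z_stat <- function(r_a, r_b, n_a, n_b, warn = FALSE) {
  clip <- 1 - 1e-7
  if (warn && (any(abs(r_a) >= 1) || any(abs(r_b) >= 1)))
    warning("correlation(s) with |r| = 1 clipped before Fisher z")
  z_a <- atanh(pmin(pmax(r_a, -clip), clip))
  z_b <- atanh(pmin(pmax(r_b, -clip), clip))
  abs(z_a - z_b) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
}

group_cor <- function(values, rows, covmat) {
  v <- values[rows, , drop = FALSE]
  if (!is.null(covmat)) v <- ols_residuals(v, covmat[rows, , drop = FALSE])
  cor(v)
}

#' Network-based statistic (component-level edge inference)
#'
#' Mass-univariate edge statistics between two groups with family-wise
#' control at the level of connected suprathreshold components. The
#' default edge statistic is the Fisher-z correlation difference,
#' `|atanh(r_A) - atanh(r_B)| / sqrt(1/(n_A-3) + 1/(n_B-3))`, computed on
#' the unthresholded (residualized) association matrices; components of
#' the graph of edges exceeding `primary_threshold` are scored by extent
#' (edge count; intensity optional) against the permutation null of the
#' maximal component score.
#'
#' @param data A `morph_dataset`.
#' @param group_a,group_b Group labels (both sizes must exceed 3 for the
#'   Fisher-z variance).
#' @param primary_threshold Edge-statistic threshold (default 2.58, the
#'   two-tailed 0.01 point on the z scale; NBS results are threshold-
#'   dependent by construction).
#' @param n_perm Number of subject-reassignment permutations.
#' @param seed Master seed.
#' @param covariates Residualized within each (pseudo-)group.
#' @param statistic `"fisher_z"` (default) or `"raw_difference"`
#'   (`|r_A - r_B|`; pick a threshold on the r scale).
#' @param component_size `"extent"` (edge count, default) or
#'   `"intensity"` (sum of suprathreshold statistics).
#' @return An `nbs_result`: `edge_stat` matrix, component list (nodes,
#'   edges, extent, intensity, corrected p) and the null of maximal
#'   component sizes.
#' @export
nbs_test <- function(data, group_a, group_b, primary_threshold = 2.58,
                     n_perm = 5000, seed = 1,
                     covariates = c("age", "sex"),
                     statistic = c("fisher_z", "raw_difference"),
                     component_size = c("extent", "intensity")) {
  stopifnot(inherits(data, "morph_dataset"))
  statistic <- match.arg(statistic)
  component_size <- match.arg(component_size)
  for (g in c(group_a, group_b))
    if (!g %in% levels(data$group)) stopf("unknown group '%s'", g)
  rows_a <- which(data$group == group_a)
  rows_b <- which(data$group == group_b)
  if (length(rows_a) <= 3L || length(rows_b) <= 3L)
    stopf("both group sizes must exceed 3 (Fisher z variance needs n - 3 > 0)")
  covmat <- if (length(covariates)) make_covmat(data, covariates) else NULL
  n_a <- length(rows_a)
  n_b <- length(rows_b)
  pooled <- c(rows_a, rows_b)

  stat_for <- function(r1, r2, warn = FALSE) {
    ra <- group_cor(data$values, r1, covmat)
    rb <- group_cor(data$values, r2, covmat)
    diag(ra) <- 0
    diag(rb) <- 0
    s <- if (statistic == "fisher_z") fisher_z_stat(ra, rb, n_a, n_b, warn)
         else abs(ra - rb)
    diag(s) <- 0
    s
  }

  obs_stat <- stat_for(rows_a, rows_b, warn = TRUE)
  dimnames(obs_stat) <- list(data$regions, data$regions)
  comps <- cpp_nbs_components(obs_stat, primary_threshold)

  use_intensity <- component_size == "intensity"
  null_max <- numeric(n_perm)
  with_seed(split_seed(seed, "nbs"), {
    for (b in seq_len(n_perm)) {
      shuffled <- sample(pooled)
      s <- stat_for(shuffled[seq_len(n_a)], shuffled[-seq_len(n_a)])
      null_max[b] <- cpp_nbs_max_extent(s, primary_threshold, use_intensity)
    }
  })

  components <- list()
  if (length(comps$extent)) {
    ord <- order(comps$extent, decreasing = TRUE)
    for (ci in ord) {
      nodes <- which(comps$component == ci)
      in_comp <- which(obs_stat > primary_threshold &
                         upper.tri(obs_stat), arr.ind = TRUE)
      in_comp <- in_comp[comps$component[in_comp[, 1]] == ci, ,
                         drop = FALSE]
      edges <- data.frame(region_i = data$regions[in_comp[, 1]],
                          region_j = data$regions[in_comp[, 2]],
                          statistic = obs_stat[in_comp])
      size <- if (use_intensity) comps$intensity[ci] else comps$extent[ci]
      components[[length(components) + 1L]] <-
        list(nodes = data$regions[nodes], edges = edges,
             extent = comps$extent[ci], intensity = comps$intensity[ci],
             p_corrected = (1 + sum(null_max >= size)) / (n_perm + 1))
    }
  }

  structure(list(edge_stat = obs_stat,
                 primary_threshold = primary_threshold,
                 statistic = statistic, component_size = component_size,
                 components = components, max_extent_null = null_max,
                 group_a = group_a, group_b = group_b, n_perm = n_perm,
                 seed = seed), class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s vs %s, threshold %.2f (%s), %d permutations\n",
              x$group_a, x$group_b, x$primary_threshold, x$statistic,
              x$n_perm))
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (i in seq_along(x$components)) {
      cmp <- x$components[[i]]
      cat(sprintf("  component %d: %d nodes, %d edges, p = %.4f\n", i,
                  length(cmp$nodes), cmp$extent, cmp$p_corrected))
    }
  }
  invisible(x)
}

#' Tabular summary of metric and NBS contrasts
#'
#' @param results List of `difference_result` objects (optionally named
#'   by contrast; default names are `"A-B"`).
#' @param nbs Optional list of `nbs_result` objects.
#' @return A `contrast_report`: a metric x contrast x density table with
#'   observed differences, p, q and a significance flag, plus NBS
#'   component listings with region labels.
#' @export
contrast_report <- function(results, nbs = list()) {
  if (inherits(results, "difference_result")) results <- list(results)
  if (!length(results)) stopf("results must be non-empty")
  if (inherits(nbs, "nbs_result")) nbs <- list(nbs)
  rows <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    label <- names(results)[i]
    if (is.null(label) || !nzchar(label))
      label <- paste0(r$group_a, "-", r$group_b)
    for (m in r$metrics)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = label, metric = m, density = r$densities,
        observed_diff = r$observed[, m], p = r$p[, m], q = r$q[, m],
        significant = !is.na(r$q[, m]) & r$q[, m] < 0.05)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  nbs_tab <- NULL
  if (length(nbs)) {
    nrows <- list()
    for (i in seq_along(nbs)) {
      x <- nbs[[i]]
      label <- names(nbs)[i]
      if (is.null(label) || !nzchar(label))
        label <- paste0(x$group_a, "-", x$group_b)
      if (!length(x$components)) next
      for (ci in seq_along(x$components)) {
        cmp <- x$components[[ci]]
        nrows[[length(nrows) + 1L]] <- data.frame(
          contrast = label, component = ci, n_nodes = length(cmp$nodes),
          extent = cmp$extent, intensity = cmp$intensity,
          p_corrected = cmp$p_corrected,
          nodes = paste(cmp$nodes, collapse = ","))
      }
    }
    if (length(nrows)) nbs_tab <- do.call(rbind, nrows)
  }
  structure(list(table = tab, nbs = nbs_tab), class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("<contrast_report>\n")
  sig <- x$table[x$table$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("significant metric differences (q < 0.05):\n")
    print(sig, row.names = FALSE, digits = 4)
  } else {
    cat("no significant metric differences (q < 0.05)\n")
  }
  if (!is.null(x$nbs)) {
    cat("NBS components:\n")
    print(x$nbs[, setdiff(colnames(x$nbs), "nodes")], row.names = FALSE,
          digits = 4)
  }
  invisible(x)
}

#' Write a contrast report as a tab-separated table
#'
#' @param report A `contrast_report`.
#' @param path Output TSV path (one row per metric x density x contrast).
#' @return `path`, invisibly.
#' @export
write_contrast_report <- function(report, path) {
  stopifnot(inherits(report, "contrast_report"))
  write.table(format_num_df(report$table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write NBS component edge lists
#'
#' One TSV per component (`<prefix>_component<k>.tsv` with columns
#' region_i, region_j, statistic).
#'
#' @param nbs An `nbs_result`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Written paths, invisibly.
#' @export
write_nbs_components <- function(nbs, dir, prefix = "nbs") {
  stopifnot(inherits(nbs, "nbs_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(nbs$components)) {
    p <- file.path(dir, sprintf("%s_component%d.tsv", prefix, i))
    write.table(format_num_df(nbs$components[[i]]$edges), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# Format numeric columns with fixed significant digits so written tables
# are byte-stable across platforms.
format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 10,
                                                format = "g")
  df
}
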