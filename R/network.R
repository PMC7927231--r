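#' Residualize morphometry on nuisance covariates
#'
#' Replaces every region column by the residuals of an ordinary
#' least-squares fit on an intercept plus the named covariates, computed
#' within each group separately so that group mean differences cannot leak
#' into the covariance structure. Cortical thickness is sensitive to age
#' and sex, hence the default covariate set.
#'
#' @param data A `morph_dataset`.
#' @param covariates Character vector drawn from `c("age", "sex")`; empty
#'   means intercept-only (column de-meaning within group).
#' @return The dataset with residualized values (`residualized = TRUE`).
#'   Idempotent: residualizing twice equals residualizing once.
#' @export
residualize <- function(data, covariates = c("age", "sex")) {
  stopifnot(inherits(data, "morph_dataset"))
  bad <- setdiff(covariates, c("age", "sex"))
  if (length(bad))
    stopf("unknown covariates: %s", paste(bad, collapse = ", "))
  covmat <- do.call(cbind, c(list(intercept = rep(1, nrow(data$values))),
                             lapply(covariates, function(v) data[[v]])))
  for (g in levels(data$group)) {
    rows <- which(data$group == g)
    if (length(rows) == 0L) next
    if (length(rows) <= ncol(covmat))
      stopf("group '%s' has %d subjects; need more than %d for covariates (%s)",
            g, length(rows), ncol(covmat),
            paste(c("intercept", covariates), collapse = ", "))
    X <- covmat[rows, , drop = FALSE]
    qx <- qr(X)
    if (qx$rank < ncol(X))
      stopf("covariate matrix is rank-deficient (collinear) in group '%s'", g)
    data$values[rows, ] <- qr.resid(qx, data$values[rows, , drop = FALSE])
  }
  data$residualized <- TRUE
  data$generator <- NULL  # factor decomposition no longer describes values
  data
}

# Internal: residuals of Y on [1, X] for one set of rows (fast path used
# inside permutation loops; no validation).
ols_residuals <- function(Y, X) {
  qr.resid(qr(X), Y)
}

#' Group association matrix
#'
#' Inter-regional Pearson correlation across the subjects of one group —
#' the structural covariance matrix that all thresholding and inference
#' steps consume. The diagonal is forced to zero.
#'
#' @param data A `morph_dataset` (typically after [residualize()]).
#' @param group Group label.
#' @return An `assoc_matrix`: symmetric `n_regions` x `n_regions`
#'   correlation matrix with attributes `group` and `n_subjects`.
#' @export
association_matrix <- function(data, group) {
  stopifnot(inherits(data, "morph_dataset"))
  if (!group %in% levels(data$group)) stopf("unknown group '%s'", group)
  rows <- which(data$group == group)
  if (length(rows) < 4L)
    stopf("group '%s' has %d subjects; at least 4 required", group,
          length(rows))
  v <- data$values[rows, , drop = FALSE]
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    stopf("zero-variance region(s): %s",
          paste(colnames(v)[sds == 0], collapse = ", "))
  r <- cor(v)
  diag(r) <- 0
  structure(list(r = r, group = group, n_subjects = length(rows),
                 regions = colnames(v)), class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d regions, group %s (n = %d)\n",
              nrow(x$r), x$group, x$n_subjects))
  invisible(x)
}

edge_count_for_density <- function(n, density) {
  as.integer(round(density * n * (n - 1) / 2))
}

min_density <- function(n) (n - 1) / (n * (n - 1) / 2)

check_densities <- function(n, densities) {
  if (any(!is.finite(densities)) || any(densities > 1))
    stopf("densities must be finite and <= 1")
  md <- min_density(n)
  if (any(densities < md))
    stopf("density %.4f below the minimal connected density %.4f (= 2/n)",
          min(densities), md)
  if (is.unsorted(densities, strictly = TRUE))
    stopf("densities must be strictly increasing")
  invisible(densities)
}

build_network <- function(order_mat, m, n, regions, density) {
  adjacency <- matrix(0L, n, n, dimnames = list(regions, regions))
  idx <- order_mat[seq_len(m), , drop = FALSE]
  adjacency[idx] <- 1L
  adjacency[idx[, c(2, 1), drop = FALSE]] <- 1L
  structure(list(adjacency = adjacency, density = density, n_edges = m,
                 regions = regions), class = "binary_network")
}

#' Threshold an association matrix at a fixed edge density
#'
#' Builds the maximum spanning tree on the correlation weights first
#' (guaranteeing a connected network), then adds the remaining edges in
#' decreasing correlation order until `round(density * n(n-1)/2)` edges
#' are present. Ties are broken by lexicographic node-pair order so
#' results are bit-reproducible. With the default `"positive"` ranking,
#' non-positive correlations are not eligible beyond the spanning
#' backbone (structural covariance treats negative covariance as
#' non-edges); `"absolute"` ranks by `|r|` instead.
#'
#' @param assoc An `assoc_matrix`.
#' @param density Target edge density in `(2/n, 1]`.
#' @param ranking `"positive"` (default) or `"absolute"`.
#' @return A `binary_network`: connected 0/1 adjacency with exactly the
#'   prescribed edge count.
#' @export
threshold_at_density <- function(assoc, density,
                                 ranking = c("positive", "absolute")) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  ranking <- match.arg(ranking)
  n <- nrow(assoc$r)
  check_densities(n, density)
  m <- edge_count_for_density(n, density)
  ord <- cpp_edge_order(assoc$r, ranking == "absolute")
  if (m > ord$n_candidates)
    stopf(paste0("density %.3f needs %d edges but only %d candidates exist ",
                 "(non-positive correlations excluded; consider ranking = ",
                 "'absolute')"), density, m, ord$n_candidates)
  build_network(ord$order, m, n, assoc$regions, density)
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (density %.3f)\n",
              nrow(x$adjacency), x$n_edges, x$density))
  invisible(x)
}

#' Threshold across a density sweep
#'
#' One connected binary network per density; by construction the sweeps
#' are nested (the edge set at a lower density is contained in the edge
#' set at any higher density).
#'
#' @param assoc An `assoc_matrix`.
#' @param densities Strictly increasing densities, all `>= 2/n`.
#' @param ranking See [threshold_at_density()].
#' @return A `density_sweep`: list with `densities` and `networks`.
#' @export
density_sweep <- function(assoc, densities = default_densities(),
                          ranking = c("positive", "absolute")) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  ranking <- match.arg(ranking)
  n <- nrow(assoc$r)
  check_densities(n, densities)
  ord <- cpp_edge_order(assoc$r, ranking == "absolute")
  networks <- lapply(densities, function(d) {
    m <- edge_count_for_density(n, d)
    if (m > ord$n_candidates)
      stopf("density %.3f needs %d edges but only %d candidates exist",
            d, m, ord$n_candidates)
    build_network(ord$order, m, n, assoc$regions, d)
  })
  structure(list(densities = densities, networks = networks,
                 group = assoc$group), class = "density_sweep")
}

#' @export
print.density_sweep <- function(x, ...) {
  cat(sprintf("<density_sweep> %d networks, densities %s\n",
              length(x$networks),
              paste(format(x$densities), collapse = ", ")))
  invisible(x)
}

# ---- internal fast path used by the inference and prediction modules ----

# Residualize (within the given rows), correlate, sweep, and return the
# density x metric matrix in canonical metric order (metric_names()).
group_sweep_metrics <- function(values, rows, covmat, edge_counts, want,
                                absolute_rank, n_restarts, seed) {
  v <- values[rows, , drop = FALSE]
  if (!is.null(covmat)) v <- ols_residuals(v, covmat[rows, , drop = FALSE])
  r <- cor(v)
  diag(r) <- 0
  cpp_sweep_metrics(r, edge_counts, want, absolute_rank, n_restarts, seed)
}

make_covmat <- function(data, covariates) {
  if (length(covariates) == 0L)
    return(matrix(1, nrow(data$values), 1))
  do.call(cbind, c(list(rep(1, nrow(data$values))),
                   lapply(covariates, function(v) data[[v]])))
}
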