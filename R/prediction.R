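#' Jackknife pseudovalue network features per subject
#'
#' Group-level covariance networks yield one metric value per group, not
#' per subject; to feed a per-subject regression the pipeline converts
#' them into jackknife pseudovalues: for subject `s` of a group of size
#' `n`, `n * M_full - (n - 1) * M_minus_s`, where `M` is a metric at a
#' density and `M_minus_s` recomputes the whole group pipeline
#' (residualization, correlation, thresholding, metric) without `s`.
#' Features are assembled per subject as metric-by-density columns.
#'
#' @param data A `morph_dataset`.
#' @param groups Group labels whose subjects receive features (each group
#'   is jackknifed within itself; minimum size 5).
#' @param metrics Subset of [metric_names()].
#' @param densities Density grid.
#' @param covariates Residualized within each leave-one-out subsample.
#' @param n_restarts,seed Louvain settings.
#' @param ranking Edge ranking, see [threshold_at_density()].
#' @return A `feature_table`: subjects x features numeric matrix with
#'   attributes `provenance = "jackknife"` and `groups`. Feature columns
#'   undefined in any leave-one-out network are dropped with a message.
#' @export
jackknife_features <- function(data, groups,
                               metrics = c("modularity", "transitivity",
                                           "assortativity"),
                               densities = default_densities(),
                               covariates = c("age", "sex"),
                               n_restarts = 20, seed = 1,
                               ranking = c("positive", "absolute")) {
  stopifnot(inherits(data, "morph_dataset"))
  ranking <- match.arg(ranking)
  want <- metric_want(metrics)
  sel <- which(want)
  n_reg <- ncol(data$values)
  check_densities(n_reg, densities)
  edge_counts <- vapply(densities, edge_count_for_density, integer(1),
                        n = n_reg)
  covmat <- if (length(covariates)) make_covmat(data, covariates) else NULL
  # metric varies fastest within each density, matching as.vector(t(.))
  feat_names <- as.vector(vapply(densities, function(d)
    sprintf("%s_d%.2f", metric_names()[sel], d), character(length(sel))))

  base_seed <- split_seed(seed, "jackknife")
  rows_all <- integer(0)
  feats <- NULL
  for (g in groups) {
    if (!g %in% levels(data$group)) stopf("unknown group '%s'", g)
    rows <- which(data$group == g)
    n_g <- length(rows)
    if (n_g < 5L) stopf("group '%s' has %d subjects; jackknife needs >= 5",
                        g, n_g)
    full <- group_sweep_metrics(data$values, rows, covmat, edge_counts,
                                want, ranking == "absolute", n_restarts,
                                base_seed)
    gf <- matrix(NA_real_, n_g, length(feat_names))
    for (s in seq_len(n_g)) {
      loo <- group_sweep_metrics(data$values, rows[-s], covmat,
                                 edge_counts, want,
                                 ranking == "absolute", n_restarts,
                                 base_seed)
      pseudo <- n_g * full[, sel, drop = FALSE] -
        (n_g - 1) * loo[, sel, drop = FALSE]
      gf[s, ] <- as.vector(t(pseudo))  # metric fastest, density outer
    }
    rows_all <- c(rows_all, rows)
    feats <- rbind(feats, gf)
  }
  colnames(feats) <- feat_names
  rownames(feats) <- rownames(data$values)[rows_all]

  drop <- which(apply(feats, 2, anyNA))
  if (length(drop)) {
    msg("dropping %d feature(s) undefined in some leave-one-out network: %s",
        length(drop), paste(colnames(feats)[drop], collapse = ", "))
    feats <- feats[, -drop, drop = FALSE]
  }
  structure(feats, provenance = "jackknife", groups = groups,
            class = c("feature_table", "matrix", "array"))
}

#' Cross-validated support vector regression of a clinical score
#'
#' k-fold cross-validation repeated `n_repetitions` times with seeded
#' fold shuffles. Features are standardized inside each training fold
#' only (the fold's mean/sd applied to its held-out fold) and an
#' epsilon-SVR (linear kernel by default) is fit per fold; predictions
#' pooled over a repetition's held-out folds give that repetition's
#' regression coefficient, the Pearson correlation between predicted and
#' observed scores (point-biserial for a binary score such as aura).
#'
#' @param features A numeric matrix or `feature_table` (subjects x
#'   features).
#' @param scores Numeric vector, one score per subject (no missing
#'   values; subset subjects first).
#' @param k Folds (default 10).
#' @param n_repetitions Repeated cross-validations (default 10; one
#'   coefficient each).
#' @param seed Master seed for the fold shuffles.
#' @param kernel,cost,epsilon Passed to [e1071::svm()] (linear kernel
#'   default: small n, many features).
#' @param score_name Stored label for reporting.
#' @return An `svr_result` holding the per-repetition coefficients.
#' @export
svr_crossval <- function(features, scores, k = 10, n_repetitions = 10,
                         seed = 1, kernel = "linear", cost = 1,
                         epsilon = 0.1, score_name = "score") {
  features <- unclass(features)
  if (!is.matrix(features)) stopf("features must be a matrix")
  n <- nrow(features)
  if (length(scores) != n)
    stopf("scores length (%d) does not match feature rows (%d)",
          length(scores), n)
  if (anyNA(scores) || anyNA(features))
    stopf("features and scores must be complete; subset subjects first")
  if (sd(scores) == 0)
    stopf("constant score vector: regression coefficient undefined")
  if (k > n) stopf("k = %d folds exceed n = %d subjects", k, n)

  coefs <- numeric(n_repetitions)
  for (rep_i in seq_len(n_repetitions)) {
    fold <- with_seed(split_seed(seed, paste0("cvrep:", rep_i)),
                      sample(rep(seq_len(k), length.out = n)))
    pred <- numeric(n)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      mu <- colMeans(features[train, , drop = FALSE])
      sdv <- apply(features[train, , drop = FALSE], 2, sd)
      sdv[sdv == 0] <- 1
      xtr <- scale(features[train, , drop = FALSE], mu, sdv)
      xte <- scale(features[test, , drop = FALSE], mu, sdv)
      fit <- e1071::svm(x = xtr, y = scores[train], type = "eps-regression",
                        kernel = kernel, cost = cost, epsilon = epsilon,
                        scale = FALSE)
      pred[test] <- as.numeric(stats::predict(fit, xte))
    }
    coefs[rep_i] <- cor(pred, scores)
  }
  structure(list(score_name = score_name, coefficients = coefs, k = k,
                 n_repetitions = n_repetitions,
                 borderline_threshold = 0.5, seed = seed),
            class = "svr_result")
}

#' @export
print.svr_result <- function(x, ...) {
  cat(sprintf("<svr_result> %s: median r = %.3f over %d x %d-fold CV\n",
              x$score_name, median(x$coefficients), x$n_repetitions, x$k))
  invisible(x)
}

#' Robustness verdict for an SVR result
#'
#' A prediction is called robust when the median per-repetition
#' regression coefficient strictly exceeds the 0.5 borderline.
#'
#' @param result An `svr_result`.
#' @return List with `verdict` (`"robust"`/`"not robust"`), `robust`
#'   logical, `median_coefficient`, and per-repetition flags.
#' @export
robustness_verdict <- function(result) {
  stopifnot(inherits(result, "svr_result"))
  if (!length(result$coefficients)) stopf("empty result")
  med <- median(result$coefficients)
  robust <- med > result$borderline_threshold
  list(verdict = if (robust) "robust" else "not robust", robust = robust,
       median_coefficient = med,
       per_repetition = result$coefficients > result$borderline_threshold)
}
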