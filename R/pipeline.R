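#' Read and validate a run configuration
#'
#' YAML configuration with mandatory `seed` and exactly one of `input`
#' (paths `morphometry` + `metadata`) or `generator` (arguments for
#' [cohort_spec()], plus optional `effect` and `score_links`). Optional
#' keys: `atlas`, `modality`, `densities` (`from`/`to`/`by` or a list),
#' `n_perm`, `nbs_threshold`, `contrasts` (list of two-label lists),
#' `covariates`, `ranking` (`positive`/`absolute` edge ranking), `svr`
#' (`scores`, `groups`, `metrics`, `k`, `n_repetitions`), `out_dir`.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stopf("config must set a seed")
  has_input <- !is.null(cfg$input)
  has_gen <- !is.null(cfg$generator)
  if (has_input == has_gen)
    stopf("config must set exactly one of 'input' or 'generator'")
  if (has_input && (is.null(cfg$input$morphometry) ||
                    is.null(cfg$input$metadata)))
    stopf("input config needs 'morphometry' and 'metadata' paths")
  cfg$atlas <- cfg$atlas %||% "desikan68"
  cfg$modality <- cfg$modality %||%
    if (cfg$atlas == "desikan68") "cortical_thickness" else
      "subcortical_volume"
  if (is.null(cfg$densities)) {
    cfg$densities <- default_densities()
  } else if (is.list(cfg$densities) && !is.null(cfg$densities$from)) {
    cfg$densities <- seq(cfg$densities$from, cfg$densities$to,
                         by = cfg$densities$by)
  } else {
    cfg$densities <- as.numeric(unlist(cfg$densities))
  }
  cfg$n_perm <- cfg$n_perm %||% 5000
  cfg$nbs_threshold <- cfg$nbs_threshold %||% 2.58
  cfg$covariates <- cfg$covariates %||% c("age", "sex")
  cfg$ranking <- cfg$ranking %||% "positive"
  if (!cfg$ranking %in% c("positive", "absolute"))
    stopf("ranking must be 'positive' or 'absolute'")
  cfg$metrics <- cfg$metrics %||% c("modularity", "transitivity",
                                    "assortativity", "clustering",
                                    "node_betweenness", "edge_betweenness")
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_cohort_spec <- function(cfg) {
  g <- cfg$generator
  sizes <- unlist(g$group_sizes %||% list(HC = 19, EM = 17, CM = 12))
  args <- list(group_sizes = sizes, modality = cfg$modality,
               seed = as.integer(cfg$seed))
  for (k in c("n_regions", "base_mean", "base_sd", "noise_sd",
              "latent_dim", "block_sizes", "global_share", "age_slope",
              "sex_offset"))
    if (!is.null(g[[k]])) args[[k]] <- unlist(g[[k]])
  do.call(cohort_spec, args)
}

#' Run the full analysis pipeline from a configuration
#'
#' Generates or reads the cohort, then runs permutation tests and the
#' network-based statistic for every configured contrast and the SVR
#' prediction for every configured score, writing all artifacts (tables,
#' component edge lists, report) into the run directory. Re-running with
#' the same configuration yields byte-identical outputs.
#'
#' @param config A `run_config` (see [read_run_config()]) or a list with
#'   the same structure.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stopf("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  data <- stage("load-data", {
    if (!is.null(config$generator)) {
      d <- generate_cohort(config_cohort_spec(config))
      eff <- config$generator$effect
      if (!is.null(eff))
        d <- plant_effect(d, effect_spec(eff$target_group,
                                         unlist(eff$target_regions),
                                         eff$decorrelation %||% 0,
                                         eff$thickness_shift %||% 0))
      d
    } else {
      mt <- read_morphometry_table(config$input$morphometry, config$atlas)
      md <- read_metadata(config$input$metadata)
      morphometry_dataset(mt$values, md, config$modality)
    }
  })

  svr_cfg <- config$svr
  if (!is.null(config$generator$score_links)) {
    stage("score-links", {
      groups <- svr_cfg$groups %||% setdiff(levels(data$group), "HC")
      ft <- jackknife_features(data, groups,
                               metrics = svr_cfg$metrics %||%
                                 c("modularity", "transitivity",
                                   "assortativity"),
                               densities = config$densities,
                               covariates = config$covariates,
                               seed = seed, ranking = config$ranking)
      links <- lapply(config$generator$score_links, function(l)
        score_link_spec(l$score, unlist(l$weights), l$intercept %||% 0,
                        l$noise_sd %||% 0))
      # template rows for subjects outside the linked groups stay as-is;
      # linked scores are defined on the feature-table subjects only
      full <- matrix(0, nrow(data$values), ncol(ft),
                     dimnames = list(rownames(data$values), colnames(ft)))
      full[rownames(ft), ] <- ft
      data <- attach_scores(data, links, full, seed = seed)
      for (l in links)
        data$scores[[l$score]][!rownames(data$values) %in% rownames(ft)] <-
          NA_real_
    })
  }

  stage("write-dataset", {
    write_morphometry_table(data, file.path(out_dir, "morphometry.tsv"))
    write_metadata(data, file.path(out_dir, "metadata.tsv"))
  })

  contrasts <- config$contrasts %||% {
    gl <- levels(data$group)
    utils::combn(gl, 2, simplify = FALSE)
  }
  results <- list()
  nbs_list <- list()
  stage("contrasts", {
    for (ct in contrasts) {
      ct <- unlist(ct)
      label <- paste0(ct[1], "-", ct[2])
      results[[label]] <- permutation_test(
        data, ct[1], ct[2], metrics = config$metrics,
        densities = config$densities, covariates = config$covariates,
        n_perm = config$n_perm, seed = seed, ranking = config$ranking)
      nbs_list[[label]] <- nbs_test(
        data, ct[1], ct[2], primary_threshold = config$nbs_threshold,
        n_perm = config$n_perm, seed = seed,
        covariates = config$covariates)
      write_nbs_components(nbs_list[[label]], out_dir,
                           prefix = paste0("nbs_", label))
    }
  })
  report <- contrast_report(results, nbs_list)
  write_contrast_report(report, file.path(out_dir, "contrasts.tsv"))

  svr_results <- list()
  if (!is.null(svr_cfg)) {
    stage("svr", {
      groups <- svr_cfg$groups %||% setdiff(levels(data$group), "HC")
      ft <- jackknife_features(data, groups,
                               metrics = svr_cfg$metrics %||%
                                 c("modularity", "transitivity",
                                   "assortativity"),
                               densities = config$densities,
                               covariates = config$covariates,
                               seed = seed, ranking = config$ranking)
      for (sc in unlist(svr_cfg$scores)) {
        y <- data$scores[rownames(ft), sc]
        keep <- !is.na(y)
        if (sum(keep) < 2 * (svr_cfg$k %||% 10)) {
          msg("score '%s': only %d subjects with values; skipped", sc,
              sum(keep))
          next
        }
        svr_results[[sc]] <- svr_crossval(
          ft[keep, , drop = FALSE], y[keep], k = svr_cfg$k %||% 10,
          n_repetitions = svr_cfg$n_repetitions %||% 10, seed = seed,
          score_name = sc)
      }
      if (length(svr_results))
        write_svr_results(svr_results, file.path(out_dir, "svr.tsv"))
    })
  }

  stage("report", {
    lines <- c("structural covariance network pipeline run",
               sprintf("config_hash: %s", content_hash(unclass(config))),
               sprintf("seed: %d", seed),
               sprintf("subjects: %d  regions: %d", nrow(data$values),
                       ncol(data$values)),
               sprintf("contrasts: %s", paste(names(results),
                                              collapse = ", ")),
               "",
               utils::capture.output(print(report)))
    for (sc in names(svr_results)) {
      v <- robustness_verdict(svr_results[[sc]])
      lines <- c(lines, sprintf("SVR %s: median r = %.4f (%s)", sc,
                                v$median_coefficient, v$verdict))
    }
    writeLines(lines, file.path(out_dir, "report.txt"))
  })
  invisible(out_dir)
}
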