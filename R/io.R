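#' Write a morphometry table
#'
#' Tab-separated, FreeSurfer `aparcstats2table` dialect: first column the
#' subject ID, remaining columns the region labels.
#'
#' @param data A `morph_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morphometry_table <- function(data, path) {
  stopifnot(inherits(data, "morph_dataset"))
  df <- data.frame(subject = rownames(data$values),
                   formatC(data$values, digits = 15, format = "g"),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a morphometry table
#'
#' Validates the header against the chosen atlas label list (regions may
#' appear in any order and are reordered canonically) and every cell as
#' numeric.
#'
#' @param path Tab-separated table: first column subject ID, header row of
#'   region labels.
#' @param atlas `"desikan68"` or `"subcortical19"`.
#' @return Named list with `values` (subjects x regions matrix) and
#'   `subjects`.
#' @export
read_morphometry_table <- function(path,
                                   atlas = c("desikan68", "subcortical19")) {
  atlas <- match.arg(atlas)
  expected <- atlas_regions(atlas)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stopf("morphometry table needs subject + region columns")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stopf("duplicate subject ID(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labels <- colnames(df)[-1]
  unknown <- setdiff(labels, expected)
  missing <- setdiff(expected, labels)
  if (length(unknown) || length(missing))
    stopf("atlas mismatch for %s%s%s", atlas,
          if (length(unknown)) paste0("; unknown: ",
                                      paste(unknown, collapse = ", "))
          else "",
          if (length(missing)) paste0("; missing: ",
                                      paste(missing, collapse = ", "))
          else "")
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stopf("non-numeric value '%s' at row %d, column '%s'",
          vals[bad[1], bad[2]], bad[1], labels[bad[2]])
  }
  dimnames(num) <- list(ids, labels)
  num <- num[, expected, drop = FALSE]
  msg("read %d subjects x %d regions from %s", nrow(num), ncol(num), path)
  list(values = num, subjects = ids)
}

#' Write a subject metadata table
#'
#' Tab-separated: subject ID, group, age, sex (written as F/M), and one
#' column per clinical score (`NA` written as `N/A`, the convention for
#' scores undefined in controls).
#'
#' @param data A `morph_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(data, path) {
  stopifnot(inherits(data, "morph_dataset"))
  df <- data.frame(subject = rownames(data$values),
                   group = as.character(data$group),
                   age = formatC(data$age, digits = 10, format = "g"),
                   sex = ifelse(data$sex == 1, "M", "F"))
  for (s in colnames(data$scores))
    df[[s]] <- ifelse(is.na(data$scores[[s]]), "N/A",
                      formatC(data$scores[[s]], digits = 10, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' @param path Tab-separated table with columns `subject`, `group`,
#'   `age`, `sex` (F/M or 0/1; stored as F = 0, M = 1) and optional score
#'   columns (`N/A` stored as missing).
#' @return Data frame of validated metadata.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", "N/A"),
                   colClasses = "character")
  need <- c("subject", "group", "age", "sex")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject))
    stopf("duplicate subject ID(s): %s",
          paste(unique(df$subject[duplicated(df$subject)]), collapse = ", "))
  age <- as.numeric(df$age)
  if (anyNA(age)) stopf("non-numeric age value(s)")
  if (any(age < 0)) stopf("negative age value(s)")
  sex_raw <- toupper(df$sex)
  if (!all(sex_raw %in% c("F", "M", "0", "1")))
    stopf("sex must be coded F/M or 0/1")
  sex <- ifelse(sex_raw %in% c("M", "1"), 1L, 0L)
  msg("sex coded F=0, M=1")
  out <- data.frame(subject = df$subject, group = df$group, age = age,
                    sex = sex)
  for (s in setdiff(colnames(df), need))
    out[[s]] <- as.numeric(df[[s]])
  out
}

#' Assemble a dataset from morphometry values and metadata
#'
#' @param values Subjects x regions matrix (e.g. from
#'   [read_morphometry_table()]`$values`).
#' @param metadata Data frame from [read_metadata()]; subject sets must
#'   match exactly.
#' @param modality `"cortical_thickness"` or `"subcortical_volume"`.
#' @return A `morph_dataset` (without generator state).
#' @export
morphometry_dataset <- function(values, metadata,
                                modality = c("cortical_thickness",
                                             "subcortical_volume")) {
  modality <- match.arg(modality)
  if (!setequal(rownames(values), metadata$subject))
    stopf("subject IDs in morphometry and metadata tables do not match: %s",
          paste(union(setdiff(rownames(values), metadata$subject),
                      setdiff(metadata$subject, rownames(values))),
                collapse = ", "))
  metadata <- metadata[match(rownames(values), metadata$subject), ]
  score_cols <- setdiff(colnames(metadata), c("subject", "group", "age",
                                              "sex"))
  scores <- metadata[, score_cols, drop = FALSE]
  rownames(scores) <- metadata$subject
  structure(list(values = values, regions = colnames(values),
                 modality = modality,
                 group = factor(metadata$group,
                                levels = unique(metadata$group)),
                 age = metadata$age, sex = metadata$sex, scores = scores,
                 residualized = FALSE, generator = NULL),
            class = "morph_dataset")
}

#' Write per-repetition SVR coefficients
#'
#' @param results Named list of `svr_result` objects (one per score).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_svr_results <- function(results, path) {
  if (inherits(results, "svr_result")) results <- list(results)
  rows <- lapply(results, function(r)
    data.frame(score = r$score_name, repetition = seq_along(r$coefficients),
               coefficient = formatC(r$coefficients, digits = 10,
                                     format = "g"),
               robust = r$coefficients > r$borderline_threshold))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
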