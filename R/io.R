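# File readers/writers: gold standard and submission CSVs, abundance TSVs.
# All I/O is UTF-8; labels/submissions are comma-separated, abundance
# matrices tab-separated with the feature identifier in the first column.

#' Read a gold standard CSV
#'
#' Expects a header `sample_id,label`; labels restricted to
#' `CD`/`UC`/`nonIBD`; duplicate sample ids are an error.
#'
#' @param path File path.
#' @return A `gold_standard`.
#' @export
read_gold_standard <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("gold standard file must have columns sample_id,label", call. = FALSE)
  }
  gold_standard(df)
}

#' Write a gold standard CSV
#' @param gold A `gold_standard`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  utils::write.csv(as.data.frame(gold)[c("sample_id", "label")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a submission CSV
#'
#' Expects a `sample_id` column plus one confidence column per task
#' (`IBDvsNonIBD,CDvsNonIBD,UCvsNonIBD,CDvsUC`).  Confidences must lie in
#' `[0, 1]` and cover every gold-standard sample.
#'
#' @param path File path.
#' @param gold A `gold_standard` used for coverage validation.
#' @param features_path Optional path to a `feature_id,importance` CSV with
#'   the submission's ranked feature list.
#' @inheritParams submission
#' @return A validated `submission`.
#' @export
read_submission <- function(path, gold, submission_id = basename_noext(path),
                            team_id = submission_id,
                            sub_challenge = c("SC1", "SC2"),
                            data_type = c("raw", "taxonomy", "function"),
                            method_tags = c(feature_selection = "unknown",
                                            classifier = "unknown"),
                            features_path = NULL) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(df)) {
    stop("submission file must have a sample_id column", call. = FALSE)
  }
  tasks <- intersect(task_names(), names(df))
  if (length(tasks) == 0) stop("submission file has no task columns", call. = FALSE)
  conf <- lapply(tasks, function(tk) {
    p <- stats::setNames(as.numeric(df[[tk]]), as.character(df$sample_id))
    check_confidence_range(p, context = paste0(basename(path), ":", tk))
    p
  })
  names(conf) <- tasks
  fi <- NULL
  if (!is.null(features_path)) fi <- read_feature_list(features_path)
  sub <- submission(submission_id, conf, team_id = team_id,
                    sub_challenge = sub_challenge, data_type = data_type,
                    method_tags = method_tags, feature_importances = fi)
  validate_submission(sub, gold)
  sub
}

#' Write a submission CSV
#' @param sub A `submission`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_submission <- function(sub, path) {
  stopifnot(inherits(sub, "submission"))
  ids <- names(sub$confidences[[1]])
  df <- data.frame(sample_id = ids, check.names = FALSE)
  for (tk in names(sub$confidences)) df[[tk]] <- unname(sub$confidences[[tk]][ids])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a ranked feature list CSV (`feature_id,importance`)
#' @param path File path.
#' @return Tibble with columns `feature_id`, `importance`.
#' @export
read_feature_list <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("feature_id", "importance") %in% names(df))) {
    stop("feature list must have columns feature_id,importance", call. = FALSE)
  }
  tibble::tibble(feature_id = as.character(df$feature_id),
                 importance = as.numeric(df$importance))
}

#' Write a ranked feature list CSV
#' @param features Data frame with `feature_id`, `importance`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_feature_list <- function(features, path) {
  utils::write.csv(features[c("feature_id", "importance")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated abundance matrix
#'
#' First column is the feature identifier (`TaxID` or `PathID`), remaining
#' columns are samples.  Non-numeric cells are an error naming the cell;
#' negative abundances are an error.  For taxonomy matrices a companion
#' description file (`TaxID,rank,name`) supplies the per-feature level.
#'
#' @param path File path.
#' @param kind `"taxonomy"` or `"function"`.
#' @param description_path Optional taxonomy description CSV.
#' @inheritParams abundance_matrix
#' @return An `abundance_matrix`.
#' @export
read_abundance_matrix <- function(path, kind = c("taxonomy", "function"),
                                  description_path = NULL, check_sums = TRUE,
                                  tol = 1e-6) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("abundance matrix needs at least one sample column", call. = FALSE)
  ids <- as.character(df[[1]])
  samples <- names(df)[-1]
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric abundance '%s' at row %s, column %s",
                   df[[j + 1]][bad[1]], ids[bad[1]], samples[j]), call. = FALSE)
    }
    m[, j] <- v
  }
  level <- NULL
  if (kind == "taxonomy" && !is.null(description_path)) {
    desc <- utils::read.csv(description_path, colClasses = "character",
                            fileEncoding = "UTF-8")
    if (!all(c("TaxID", "rank") %in% names(desc))) {
      stop("taxonomy description must have columns TaxID,rank,name", call. = FALSE)
    }
    level <- stats::setNames(desc$rank, desc$TaxID)[ids]
    if (anyNA(level)) {
      stop("description file missing TaxID(s): ",
           paste(ids[is.na(level)], collapse = ", "), call. = FALSE)
    }
  }
  abundance_matrix(m, kind = kind, level = unname(level), check_sums = check_sums,
                   tol = tol)
}

#' Write an abundance matrix TSV (plus optional taxonomy description CSV)
#' @param x An `abundance_matrix`.
#' @param path File path for the TSV.
#' @param description_path Optional path for the `TaxID,rank,name` companion.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(x, path, description_path = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  id_col <- if (x$kind == "taxonomy") "TaxID" else "PathID"
  df <- data.frame(rownames(x$abundance), x$abundance, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(description_path) && x$kind == "taxonomy") {
    desc <- data.frame(TaxID = rownames(x$abundance), rank = unname(x$level),
                       name = rownames(x$abundance))
    utils::write.csv(desc, description_path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

basename_noext <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Challenge configuration
#'
#' Central configuration with documented defaults matching the challenge's
#' published settings: binarisation threshold 0.5, 10,000 null draws,
#' 95th-percentile significance with interpolated percentiles, the
#' restricted precision-recall threshold grid, 5-fold cross-validation with
#' 10 repeats, and consensus signature sizes 4 to 200.  A YAML file can
#' override any entry.
#'
#' @param path Optional YAML file with overrides.
#' @param ... Named overrides applied after the file.
#' @return Named list of settings.
#' @export
challenge_config <- function(path = NULL, ...) {
  cfg <- list(
    threshold = 0.5,
    null_draws = 10000,
    percentile = 0.95,
    percentile_type = "interpolation",
    aupr_grid = "challenge",
    cv_folds = 5,
    cv_repeats = 10,
    signature_sizes = c(4L, 200L),
    subset_cap = 1000,
    seed = 1L
  )
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}
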