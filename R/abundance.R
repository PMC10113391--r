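# Relative-abundance matrices (taxonomy and pathway profiles).

#' Construct an abundance matrix
#'
#' Feature-by-sample grid of non-negative abundances.  Taxonomy matrices
#' carry a per-feature taxonomic level annotation (Species ... Superkingdom)
#' and are expected to sum to 100 within each level and sample, mirroring
#' percent relative abundances re-estimated per taxonomic rank; pathway
#' matrices carry no level annotation and no sum constraint.
#'
#' @param abundance Numeric matrix, features in rows (rownames are
#'   TaxID/PathID), samples in columns.
#' @param kind `"taxonomy"` or `"function"`.
#' @param level Character vector of per-feature levels (taxonomy only);
#'   a single value is recycled.
#' @param check_sums For taxonomy, verify the per-level per-sample sum of
#'   100 within `tol`.
#' @param tol Tolerance on the 100% sum check.
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(abundance, kind = c("taxonomy", "function"),
                             level = NULL, check_sums = TRUE, tol = 1e-6) {
  kind <- match.arg(kind)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance matrix needs feature rownames and sample colnames", call. = FALSE)
  }
  if (!is.numeric(abundance) || anyNA(abundance)) {
    stop("abundance matrix must be numeric with no missing values", call. = FALSE)
  }
  if (any(abundance < 0)) {
    bad <- which(abundance < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at feature %s, sample %s",
                 rownames(abundance)[bad[1]], colnames(abundance)[bad[2]]),
         call. = FALSE)
  }
  if (kind == "taxonomy") {
    if (is.null(level)) level <- "Species"
    level <- rep_len(level, nrow(abundance))
    names(level) <- rownames(abundance)
    if (check_sums) {
      for (lv in unique(level)) {
        sums <- colSums(abundance[level == lv, , drop = FALSE])
        off <- which(abs(sums - 100) > tol)
        if (length(off) > 0) {
          stop(sprintf("taxonomy level %s: abundances of sample %s sum to %.6f, not 100",
                       lv, names(sums)[off[1]], sums[off[1]]), call. = FALSE)
        }
      }
    }
  } else {
    level <- NULL
  }
  structure(list(abundance = abundance, kind = kind, level = level),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<%s abundance matrix: %d features x %d samples>\n", x$kind,
              nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$abundance)

#' Subset features at a taxonomic level
#'
#' @param x An `abundance_matrix`.
#' @param level Level name, e.g. `"Species"`.
#' @return Plain numeric matrix of the features annotated at that level.
#' @export
abundance_at_level <- function(x, level = "Species") {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$kind != "taxonomy") return(x$abundance)
  keep <- names(x$level)[x$level == level]
  if (length(keep) == 0) stop("no features at level ", level, call. = FALSE)
  x$abundance[keep, , drop = FALSE]
}

#' Join per-sample abundance profiles into one matrix
#'
#' Profiles produced per sample (e.g. pathway abundance files) rarely list
#' the same feature set; features absent from a sample's profile receive
#' abundance 0 in the joined matrix.
#'
#' @param profiles Named list (names are sample ids) of named numeric
#'   vectors `feature_id -> abundance`.
#' @inheritParams abundance_matrix
#' @return An `abundance_matrix` over the union of features.
#' @export
join_abundance_profiles <- function(profiles, kind = c("function", "taxonomy"),
                                    level = NULL, check_sums = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  features <- sort(unique(unlist(lapply(profiles, names))))
  m <- matrix(0, nrow = length(features), ncol = length(profiles),
              dimnames = list(features, names(profiles)))
  for (s in names(profiles)) {
    p <- profiles[[s]]
    m[names(p), s] <- p
  }
  abundance_matrix(m, kind = kind, level = level, check_sums = check_sums)
}
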