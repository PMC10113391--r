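# Misclassification analysis: deduplication of binarized-identical
# submissions, per-sample misclassification rates, Shannon diversity and
# group-wise statistics.

binarized_key <- function(sub, tasks, threshold = 0.5) {
  parts <- vapply(tasks, function(task) {
    p <- sub$confidences[[task$name]]
    paste(binarize(p[sort(names(p))], threshold), collapse = "")
  }, character(1))
  paste(parts, collapse = "|")
}

#' Deduplicate binarized-identical submissions
#'
#' Submissions whose binarized (threshold 0.5) predictions coincide on
#' every task are grouped; one representative per group (the
#' lexicographically smallest submission id) is retained, so that teams
#' submitting near-copies do not bias per-sample misclassification rates.
#'
#' @param subs List of `submission` objects.
#' @param tasks Task list; defaults to the four challenge tasks.
#' @param threshold Binarisation threshold.
#' @return List of retained submissions; the grouping is attached as the
#'   `"groups"` attribute (tibble `submission_id`, `key`, `retained`).
#' @export
dedup_binarized <- function(subs, tasks = challenge_tasks(), threshold = 0.5) {
  stopifnot(length(subs) >= 1)
  ids <- vapply(subs, function(s) s$submission_id, character(1))
  keys <- vapply(subs, binarized_key, character(1), tasks = tasks,
                 threshold = threshold)
  ord <- order(keys, ids)
  retained_ids <- tapply(ids, keys, function(g) sort(g)[1])
  retained <- subs[ids %in% retained_ids]
  groups <- tibble::tibble(submission_id = ids[ord], key = keys[ord],
                           retained = ids[ord] %in% retained_ids)
  attr(retained, "groups") <- groups
  retained
}

#' Per-sample misclassification rate
#'
#' Fraction of retained submissions whose binarized call differs from the
#' gold label, for one sample of one task.
#'
#' @param sample_id Sample identifier; must be in the task's scope.
#' @param task A `challenge_task`.
#' @param retained List of (deduplicated) submissions.
#' @param gold A `gold_standard`.
#' @param threshold Binarisation threshold.
#' @return Proportion in `[0, 1]`.
#' @export
misclassification_rate <- function(sample_id, task, retained, gold,
                                   threshold = 0.5) {
  cls <- gold_classes(gold, task)
  if (!sample_id %in% names(cls) || is.na(cls[[sample_id]])) {
    stop("sample ", sample_id, " is out of scope for task ", task$name,
         call. = FALSE)
  }
  calls <- vapply(retained, function(s) {
    unname(binarize(s$confidences[[task$name]], threshold)[sample_id])
  }, integer(1))
  mean(calls != cls[[sample_id]])
}

#' Misclassification rates for every in-scope sample of every task
#'
#' @param retained List of (deduplicated) submissions.
#' @param gold A `gold_standard`.
#' @param tasks Task list.
#' @param threshold Binarisation threshold.
#' @return Tibble: `sample_id`, `label`, `task`, `rate`, `n_submissions`.
#' @export
misclassification_rates <- function(retained, gold, tasks = challenge_tasks(),
                                    threshold = 0.5) {
  rows <- lapply(tasks, function(task) {
    cls <- gold_classes(gold, task)
    scope <- names(cls)[!is.na(cls)]
    calls <- vapply(retained, function(s) {
      binarize(s$confidences[[task$name]], threshold)[scope]
    }, integer(length(scope)))
    calls <- matrix(calls, nrow = length(scope))
    wrong <- calls != cls[scope]
    tibble::tibble(sample_id = scope,
                   label = gold_label_vector(gold)[scope],
                   task = task$name,
                   rate = rowMeans(wrong),
                   n_submissions = length(retained))
  })
  dplyr::bind_rows(rows)
}

#' Shannon diversity index
#'
#' `H' = -sum(p_i * ln p_i)` over the vector normalised to proportions;
#' zero entries contribute nothing.  Scale-invariant: percentages and
#' proportions give the same value.
#'
#' @param profile Non-negative abundance vector with positive sum.
#' @return The Shannon index, a non-negative real.
#' @export
shannon <- function(profile) {
  if (!is.numeric(profile) || anyNA(profile) || any(profile < 0)) {
    stop("profile must be a non-negative numeric vector", call. = FALSE)
  }
  total <- sum(profile)
  if (total <= 0) stop("all-zero profile: Shannon index undefined", call. = FALSE)
  p <- profile[profile > 0] / total
  -sum(p * log(p))
}

#' Per-sample Shannon diversity of an abundance matrix
#'
#' For taxonomy matrices the index is computed at one taxonomic level
#' (Species by default); pathway matrices use all rows.
#'
#' @param x An `abundance_matrix`.
#' @param level Taxonomic level (taxonomy matrices only).
#' @return Named numeric vector, one value per sample.
#' @export
sample_shannon <- function(x, level = "Species") {
  m <- abundance_at_level(x, level)
  apply(m, 2, shannon)
}

#' Compare misclassification rates between two groups
#'
#' Two-sided Mann-Whitney U test on the rate distributions of two
#' independent sample groups.
#'
#' @param rates_class1,rates_class2 Rate vectors of the two groups.
#' @return Tibble with `statistic` (U for the first group), `p_value`.
#' @export
group_rate_test <- function(rates_class1, rates_class2) {
  if (length(rates_class1) == 0 || length(rates_class2) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ht <- suppressWarnings(stats::wilcox.test(rates_class1, rates_class2,
                                            alternative = "two.sided",
                                            exact = FALSE))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Correlation between misclassification rate and diversity
#'
#' Spearman by default (rates are bounded proportions); Pearson available.
#' The `p < 0.05` flag mirrors the starred annotations of the challenge's
#' rate-versus-diversity panels.
#'
#' @param rates Misclassification rates.
#' @param shannon_values Matching Shannon indices.
#' @param method `"spearman"` or `"pearson"`.
#' @return Tibble with `estimate`, `p_value`, `significant`.
#' @export
rate_diversity_correlation <- function(rates, shannon_values,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(rates) == length(shannon_values))
  if (length(rates) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(rates) == 0 || stats::sd(shannon_values) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::cor.test(rates, shannon_values, method = method))
  tibble::tibble(estimate = unname(ht$estimate), p_value = ht$p.value,
                 significant = ht$p.value < 0.05)
}

#' Misclassification report joining rates with diversity
#'
#' Deduplicates the submissions, computes per-sample misclassification
#' rates for every task and attaches per-sample Shannon diversity from the
#' taxonomy and/or pathway matrices.
#'
#' @param subs List of submissions (deduplicated internally).
#' @param gold A `gold_standard`.
#' @param taxonomy,functional Optional `abundance_matrix` objects.
#' @param tasks Task list.
#' @param level Taxonomic level for diversity.
#' @param threshold Binarisation threshold.
#' @return Tibble: `sample_id`, `label`, `group` (IBD/nonIBD), `task`,
#'   `rate`, `n_submissions`, `shannon_taxonomy`, `shannon_function`.
#' @export
misclassification_report <- function(subs, gold, taxonomy = NULL,
                                     functional = NULL,
                                     tasks = challenge_tasks(),
                                     level = "Species", threshold = 0.5) {
  retained <- dedup_binarized(subs, tasks = tasks, threshold = threshold)
  rates <- misclassification_rates(retained, gold, tasks = tasks,
                                   threshold = threshold)
  rates$group <- ifelse(rates$label == "nonIBD", "nonIBD", "IBD")
  if (!is.null(taxonomy)) {
    hs <- sample_shannon(taxonomy, level = level)
    rates$shannon_taxonomy <- unname(hs[rates$sample_id])
  }
  if (!is.null(functional)) {
    hs <- sample_shannon(functional)
    rates$shannon_function <- unname(hs[rates$sample_id])
  }
  rates
}
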