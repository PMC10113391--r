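# Wisdom-of-crowd prediction aggregation: filtering, confidence
# averaging, random-subset ensembles, robustness trajectories and
# taxonomy/function pairing.

#' Filter submissions for aggregation
#'
#' To avoid over-weighting particular method combinations, one
#' seeded-random representative is kept per (team, feature-selection,
#' classifier) group.  Submissions flagged as inverted (label-swapped
#' predictions scoring better than random) are excluded first.
#'
#' @param subs List of `submission` objects.
#' @param inverted_ids Submission ids to exclude as inverted.
#' @param seed Integer seed for the per-group draw.
#' @return List of retained submissions.
#' @export
filter_for_aggregation <- function(subs, inverted_ids = character(), seed = 1L) {
  subs <- Filter(function(s) !(s$submission_id %in% inverted_ids), subs)
  if (length(subs) == 0) return(subs)
  key <- vapply(subs, function(s) {
    paste(s$team_id, s$method_tags[["feature_selection"]],
          s$method_tags[["classifier"]], sep = "/")
  }, character(1))
  ids <- vapply(subs, function(s) s$submission_id, character(1))
  set.seed(as.integer(seed))
  keep <- unlist(lapply(split(seq_along(subs), key), function(idx) {
    idx[sample.int(length(idx), 1)]
  }))
  subs[sort(keep)]
}

#' Detect candidate inverted submissions
#'
#' Advisory detector: flags submissions whose label-swapped confidences
#' (`1 - P1`) exceed the null threshold on at least `min_tasks` tasks for
#' the given metric.  Detection never excludes anything automatically;
#' feed the returned ids to [filter_for_aggregation()] if wanted.
#'
#' @param subs List of submissions.
#' @param gold A `gold_standard`.
#' @param nulls Null set from [build_null_set()].
#' @param metric Metric to check (default `"mcc"`).
#' @param min_tasks Minimum number of tasks where the inverted prediction
#'   must beat the null (default 2).
#' @return Character vector of flagged submission ids.
#' @export
detect_inverted <- function(subs, gold, nulls, metric = "mcc", min_tasks = 2) {
  flagged <- vapply(subs, function(s) {
    inv <- s
    inv$confidences <- lapply(s$confidences, function(p) 1 - p)
    sc <- score_submission(inv, gold)
    key <- paste(sc$task, metric, sep = ".")
    p95 <- vapply(key, function(k) nulls[[k]]$p95, numeric(1))
    sum(sc[[metric]] > p95) >= min_tasks
  }, logical(1))
  vapply(subs[flagged], function(s) s$submission_id, character(1))
}

#' Aggregate submissions by confidence averaging
#'
#' The aggregated prediction's confidence for a sample is the arithmetic
#' mean of the members' confidences for that sample, per task.
#' Aggregating a single submission returns it unchanged (up to identity
#' metadata).
#'
#' @param members Non-empty list of submissions with identical sample
#'   coverage.
#' @param submission_id Identifier for the aggregate.
#' @return A `submission` whose member ids are kept in the `member_ids`
#'   attribute.
#' @export
aggregate_submissions <- function(members,
                                  submission_id = paste0("agg_", length(members))) {
  stopifnot(length(members) >= 1)
  ref <- members[[1]]
  tasks <- names(ref$confidences)
  conf <- lapply(tasks, function(tk) {
    ids <- sort(names(ref$confidences[[tk]]))
    vals <- vapply(members, function(s) {
      p <- s$confidences[[tk]]
      if (!setequal(names(p), ids)) {
        stop("coverage mismatch between aggregation members (task ", tk, ")",
             call. = FALSE)
      }
      p[ids]
    }, numeric(length(ids)))
    vals <- matrix(vals, nrow = length(ids))
    stats::setNames(rowMeans(vals), ids)
  })
  names(conf) <- tasks
  out <- submission(submission_id, conf, team_id = "aggregate",
                    sub_challenge = ref$sub_challenge, data_type = ref$data_type,
                    method_tags = c(feature_selection = "aggregate",
                                    classifier = "mean"))
  attr(out, "member_ids") <- vapply(members, function(s) s$submission_id,
                                    character(1))
  out
}

# Sample up to `cap` distinct k-subsets of n members (1-based indices).
sample_combinations <- function(n, k, cap, seed) {
  if (k > n) stop("subset size exceeds pool size", call. = FALSE)
  total <- choose(n, k)
  if (total <= cap) {
    combos <- utils::combn(n, k, simplify = FALSE)
  } else {
    set.seed(as.integer(seed))
    seen <- new.env(hash = TRUE)
    combos <- vector("list", cap)
    got <- 0
    while (got < cap) {
      cand <- sort(sample.int(n, k))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1
        combos[[got]] <- cand
      }
    }
  }
  combos
}

#' Random-subset aggregation experiment
#'
#' For each subset size, scores the aggregates of randomly selected
#' member combinations (all combinations when fewer than `max_combos`
#' exist, otherwise `max_combos` distinct sampled ones; a size equal to
#' the pool yields the single all-member aggregate).
#'
#' @param pool List of submissions (already filtered for aggregation).
#' @param sizes Integer vector of subset sizes.
#' @param max_combos Cap on combinations per size (default 1000).
#' @param seed Integer seed.
#' @param gold A `gold_standard`.
#' @param tasks Task list.
#' @param grid AUPR grid.
#' @return Tibble: `size`, `combo`, `task`, `mcc`, `aupr`.
#' @export
random_subset_experiment <- function(pool, sizes, max_combos = 1000, seed = 1L,
                                     gold, tasks = challenge_tasks(),
                                     grid = "challenge") {
  n <- length(pool)
  rows <- list()
  for (k in sizes) {
    combos <- sample_combinations(n, k, max_combos, child_seed(seed, "size", k))
    for (i in seq_along(combos)) {
      agg <- aggregate_submissions(pool[combos[[i]]],
                                   submission_id = sprintf("agg_k%d_%d", k, i))
      sc <- score_submission(agg, gold, tasks = tasks, grid = grid)
      rows[[length(rows) + 1]] <-
        tibble::tibble(size = k, combo = i, task = sc$task, mcc = sc$mcc,
                       aupr = sc$aupr)
    }
  }
  dplyr::bind_rows(rows)
}

#' Robustness of aggregation to weak members
#'
#' Ranks the pool by one (task, metric), removes the three best and three
#' worst members to form the "initial" assembly, then re-scores the
#' assembly while adding back, one by one, the three worst members
#' (direction `"worst"`) or the three best (direction `"best"`).
#'
#' @param pool List of at least 7 submissions.
#' @param gold A `gold_standard`.
#' @param task Task used for ranking and scoring.
#' @param metric `"aupr"` (default) or `"mcc"`.
#' @param tasks Task list.
#' @param grid AUPR grid.
#' @return Tibble: `direction`, `step` (0 = initial assembly), `n_members`,
#'   `mcc`, `aupr`.
#' @export
robustness_experiment <- function(pool, gold, task = "IBDvsNonIBD",
                                  metric = c("aupr", "mcc"),
                                  tasks = challenge_tasks(), grid = "challenge") {
  metric <- match.arg(metric)
  if (length(pool) < 7) stop("pool must hold at least 7 submissions", call. = FALSE)
  sc <- score_submissions(pool, gold, tasks = tasks[task], grid = grid)
  ord <- order(-sc[[metric]], sc$submission_id)  # best first
  best3 <- ord[1:3]
  worst3 <- rev(ord)[1:3]  # worst first
  middle <- setdiff(seq_along(pool), c(best3, worst3))
  score_assembly <- function(idx, direction, step) {
    agg <- aggregate_submissions(pool[idx],
                                 submission_id = sprintf("asm_%s_%d", direction, step))
    s <- score_submission(agg, gold, tasks = tasks[task], grid = grid)
    tibble::tibble(direction = direction, step = step, n_members = length(idx),
                   mcc = s$mcc, aupr = s$aupr)
  }
  rows <- list()
  for (direction in c("worst", "best")) {
    additions <- if (direction == "worst") worst3 else best3
    idx <- middle
    rows[[length(rows) + 1]] <- score_assembly(idx, direction, 0L)
    for (j in 1:3) {
      idx <- c(idx, additions[j])
      rows[[length(rows) + 1]] <- score_assembly(idx, direction, j)
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare taxonomy- and function-based predictions with their aggregate
#'
#' For each matched (taxonomy, function) submission pair of a team, scores
#' both members and their two-member aggregate on one task, and tests at
#' cohort level -- with two-sided Wilcoxon signed-rank tests over the
#' paired per-submission scores -- whether the aggregate outperforms each
#' profile type.
#'
#' @param tax_subs,fun_subs Lists of submissions of the two data types,
#'   matched by `submission_id`.
#' @param gold A `gold_standard`.
#' @param task Task scored.
#' @param metric `"aupr"` or `"mcc"`.
#' @param tasks Task list.
#' @param grid AUPR grid.
#' @return List with `records` (tibble: `submission_id`, `score_taxonomy`,
#'   `score_function`, `score_aggregate`) and `tests` (tibble of paired
#'   signed-rank p-values, aggregate vs each data type).
#' @export
pair_datatype_aggregation <- function(tax_subs, fun_subs, gold,
                                      task = "IBDvsNonIBD",
                                      metric = c("aupr", "mcc"),
                                      tasks = challenge_tasks(),
                                      grid = "challenge") {
  metric <- match.arg(metric)
  tax_ids <- vapply(tax_subs, function(s) s$submission_id, character(1))
  fun_ids <- vapply(fun_subs, function(s) s$submission_id, character(1))
  if (!setequal(tax_ids, fun_ids)) {
    stop("unmatched pair(s): ",
         paste(c(setdiff(tax_ids, fun_ids), setdiff(fun_ids, tax_ids)),
               collapse = ", "), call. = FALSE)
  }
  fun_subs <- fun_subs[match(tax_ids, fun_ids)]
  recs <- lapply(seq_along(tax_subs), function(i) {
    tx <- tax_subs[[i]]; fn <- fun_subs[[i]]
    agg <- aggregate_submissions(list(tx, fn),
                                 submission_id = paste0(tx$submission_id, "_pair"))
    s <- function(sub) score_submission(sub, gold, tasks = tasks[task],
                                        grid = grid)[[metric]]
    tibble::tibble(submission_id = tx$submission_id, score_taxonomy = s(tx),
                   score_function = s(fn), score_aggregate = s(agg))
  })
  records <- dplyr::bind_rows(recs)
  paired_p <- function(a, b) {
    if (all(a == b)) return(1)
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                        exact = FALSE))$p.value
  }
  tests <- tibble::tibble(
    comparison = c("aggregate_vs_taxonomy", "aggregate_vs_function"),
    p_value = c(paired_p(records$score_aggregate, records$score_taxonomy),
                paired_p(records$score_aggregate, records$score_function)))
  list(records = records, tests = tests)
}
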