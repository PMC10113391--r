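# Random-prediction null distributions, 95th-percentile thresholds and
# score flooring.

#' Generate uniform random prediction sets
#'
#' Each set assigns an independent uniform `[0, 1]` confidence value to
#' every sample; reproducible under the seed.
#'
#' @param n_sets Number of prediction sets.
#' @param sample_ids Sample identifiers.
#' @param seed Integer seed.
#' @return Numeric matrix, one row per set, one named column per sample.
#' @export
random_predictions <- function(n_sets, sample_ids, seed = 1L) {
  stopifnot(n_sets >= 1, length(sample_ids) >= 1)
  set.seed(as.integer(seed))
  matrix(stats::runif(n_sets * length(sample_ids)), nrow = n_sets,
         dimnames = list(NULL, sample_ids))
}

# Deterministic per-(task, metric) child seed spawned from a master seed.
child_seed <- function(seed, ...) {
  label <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 1009)
  as.integer((as.numeric(seed) * 48271 + h) %% (2^31 - 2) + 1)
}

#' Build a random-prediction null distribution
#'
#' Scores `n_draws` uniform random prediction sets with the requested
#' metric over the task's in-scope samples and records the 95th-percentile
#' threshold.  One null per (task, metric) pair is shared by all
#' submissions, since it depends only on the gold standard.
#'
#' @param task A `challenge_task`.
#' @param metric `"mcc"` or `"aupr"`.
#' @param gold A `gold_standard`.
#' @param n_draws Number of random prediction sets (default 10,000).
#' @param seed Integer seed.
#' @param percentile Significance percentile (default 0.95).
#' @param percentile_type `"interpolation"` (linear between order
#'   statistics) or `"nearest_rank"`.
#' @param grid AUPR threshold grid (see [aupr()]).
#' @param threshold Binarisation threshold for the MCC.
#' @return A `null_distribution` with fields `task`, `metric`, `n_draws`,
#'   `scores`, `p95`, `seed`.
#' @export
build_null <- function(task, metric = c("mcc", "aupr"), gold, n_draws = 10000,
                       seed = 1L, percentile = 0.95,
                       percentile_type = c("interpolation", "nearest_rank"),
                       grid = "challenge", threshold = 0.5) {
  metric <- match.arg(metric)
  percentile_type <- match.arg(percentile_type)
  cls <- gold_classes(gold, task)
  scope <- names(cls)[!is.na(cls)]
  if (length(scope) == 0) stop("no samples in scope for task ", task$name, call. = FALSE)
  draws <- random_predictions(n_draws, gold$sample_id, seed = seed)
  y <- cls[scope] == 1L
  scores <- vapply(seq_len(n_draws), function(i) {
    p <- draws[i, scope]
    if (metric == "mcc") {
      pred <- ifelse(p > threshold, 1L, 2L)
      tp <- sum(pred == 1L & y); fp <- sum(pred == 1L & !y)
      fn <- sum(pred == 2L & y); tn <- sum(pred == 2L & !y)
      mcc(structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
                    class = "confusion_counts"))
    } else {
      lower <- if (grid == "challenge") 0.5 else 0
      thr <- sort(unique(c(1, lower, p[p > lower & p <= 1])), decreasing = TRUE)
      aupr_from_points(unname(p), y, thr)
    }
  }, numeric(1))
  p95 <- null_percentile(scores, percentile, percentile_type)
  structure(list(task = task$name, metric = metric, n_draws = n_draws,
                 scores = scores, p95 = p95, seed = seed,
                 percentile = percentile, percentile_type = percentile_type),
            class = "null_distribution")
}

null_percentile <- function(scores, percentile, percentile_type) {
  type <- if (percentile_type == "interpolation") 7 else 1
  unname(stats::quantile(scores, percentile, type = type, names = FALSE))
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null distribution: %s/%s, %d draws, p%g = %.4f>\n", x$task,
              x$metric, x$n_draws, 100 * x$percentile, x$p95))
  invisible(x)
}

#' Build the full set of null distributions
#'
#' One null per (task, metric); child seeds are spawned deterministically
#' from the master seed, so the whole set is reproducible.
#'
#' @param gold A `gold_standard`.
#' @param tasks Task list.
#' @param metrics Metrics to simulate.
#' @inheritParams build_null
#' @return Named list keyed `"<task>.<metric>"` of `null_distribution`s.
#' @export
build_null_set <- function(gold, tasks = challenge_tasks(),
                           metrics = c("mcc", "aupr"), n_draws = 10000,
                           seed = 1L, percentile = 0.95,
                           percentile_type = "interpolation",
                           grid = "challenge", threshold = 0.5) {
  out <- list()
  for (task in tasks) {
    for (metric in metrics) {
      out[[paste(task$name, metric, sep = ".")]] <-
        build_null(task, metric, gold, n_draws = n_draws,
                   seed = child_seed(seed, task$name, metric),
                   percentile = percentile, percentile_type = percentile_type,
                   grid = grid, threshold = threshold)
    }
  }
  out
}

#' Floor a raw score against its null threshold
#'
#' A score strictly greater than the null's 95th percentile is significant
#' and kept; a score at or below it is not better than random and is set
#' to the threshold value.
#'
#' @param raw Numeric vector of raw scores.
#' @param null A `null_distribution` (or a single numeric threshold).
#' @return Tibble with columns `raw`, `floored`, `significant`.
#' @export
floor_and_flag <- function(raw, null) {
  p95 <- if (inherits(null, "null_distribution")) null$p95 else as.numeric(null)
  significant <- raw > p95
  tibble::tibble(raw = raw, floored = ifelse(significant, raw, p95),
                 significant = significant)
}

#' Attach significance flags and floored scores to a score table
#'
#' @param scores Score tibble from [score_submissions()].
#' @param nulls Null set from [build_null_set()].
#' @return The score tibble with columns `mcc_p95`, `mcc_significant`,
#'   `mcc_floored` and the `aupr` equivalents.
#' @export
add_significance <- function(scores, nulls) {
  for (metric in c("mcc", "aupr")) {
    key <- paste(scores$task, metric, sep = ".")
    missing <- setdiff(unique(key), names(nulls))
    if (length(missing) > 0) {
      stop("no null distribution for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    p95 <- vapply(key, function(k) nulls[[k]]$p95, numeric(1))
    raw <- scores[[metric]]
    sig <- raw > p95
    scores[[paste0(metric, "_p95")]] <- unname(p95)
    scores[[paste0(metric, "_significant")]] <- unname(sig)
    scores[[paste0(metric, "_floored")]] <- unname(ifelse(sig, raw, p95))
  }
  scores
}
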