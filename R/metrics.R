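# Scoring metrics: confusion counts, Matthews correlation coefficient and
# the area under the precision-recall curve on confidence-value predictions.

#' Binarize confidence values
#'
#' Class 1 iff `P1 > threshold`; a value exactly at the threshold goes to
#' class 2, so a random guess sitting exactly at 0.5 does not inflate
#' positive calls.
#'
#' @param confidences Named numeric vector `sample_id -> P1` in `[0, 1]`.
#' @param threshold Binarisation threshold in `(0, 1)`; default 0.5.
#' @return Named integer vector of classes (1 or 2).
#' @export
binarize <- function(confidences, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  check_confidence_range(confidences)
  stats::setNames(ifelse(confidences > threshold, 1L, 2L), names(confidences))
}

#' Confusion counts for a task
#'
#' Counts are computed only over samples whose gold label belongs to the
#' task's two classes; all other samples are ignored.  Class 1 is the
#' positive class.
#'
#' @param pred Named integer vector of predicted classes (1/2) covering the
#'   scored samples.
#' @param gold A `gold_standard`.
#' @param task A `challenge_task`.
#' @return A `confusion_counts` list with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, gold, task) {
  cls <- gold_classes(gold, task)
  scope <- names(cls)[!is.na(cls)]
  if (length(scope) == 0) stop("no samples in scope for task ", task$name, call. = FALSE)
  missing <- setdiff(scope, names(pred))
  if (length(missing) > 0) {
    stop("predictions missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- pred[scope]
  g <- cls[scope]
  counts <- list(tp = sum(p == 1L & g == 1L), fp = sum(p == 1L & g == 2L),
                 tn = sum(p == 2L & g == 2L), fn = sum(p == 2L & g == 1L))
  structure(counts, class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' standard convention of 0 when any marginal is zero (required because
#' degenerate predictions occur in the random null).
#'
#' @param counts A `confusion_counts`, or `tp` as a number.
#' @param fp,tn,fn Counts when given individually.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (inherits(counts, "confusion_counts")) {
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  } else {
    tp <- counts
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Area under the precision-recall curve
#'
#' Precision and recall are computed at each threshold `t` of a moving
#' grid (predict class 1 when `P1 >= t`) and the curve is integrated with
#' a right-continuous step rule: each recall increment contributes the
#' precision attained at that threshold (the average-precision rule).
#'
#' The default `"challenge"` grid moves from 1 to 0.5 -- all distinct
#' confidence values in `(0.5, 1]` plus the endpoints 1 and 0.5 -- so
#' recall may not reach 1 and the area is the partial area over the
#' explored recall range.  The `"full"` grid spans `[0, 1]` and equals
#' classical average precision.
#'
#' @param confidences Named numeric vector `sample_id -> P1`.
#' @param gold A `gold_standard`.
#' @param task A `challenge_task`.
#' @param grid `"challenge"` (1 down to 0.5) or `"full"` (1 down to 0).
#' @param integration `"step"` (default, average-precision rule) or
#'   `"trapezoid"`.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(confidences, gold, task, grid = c("challenge", "full"),
                 integration = c("step", "trapezoid")) {
  grid <- match.arg(grid)
  integration <- match.arg(integration)
  check_confidence_range(confidences)
  cls <- gold_classes(gold, task)
  scope <- names(cls)[!is.na(cls)]
  if (length(scope) == 0) stop("no samples in scope for task ", task$name, call. = FALSE)
  missing <- setdiff(scope, names(confidences))
  if (length(missing) > 0) {
    stop("confidences missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- unname(confidences[scope])
  y <- cls[scope] == 1L
  if (!any(y)) stop("no class-1 samples in scope: precision undefined", call. = FALSE)
  lower <- if (grid == "challenge") 0.5 else 0
  thr <- sort(unique(c(1, lower, p[p > lower & p <= 1])), decreasing = TRUE)
  aupr_from_points(p, y, thr, integration)
}

# Shared step/trapezoid integrator over a descending threshold grid.
aupr_from_points <- function(p, y, thr, integration = "step") {
  n_pos <- sum(y)
  prev_recall <- 0
  prev_precision <- 1
  area <- 0
  for (t in thr) {
    called <- p >= t
    tp <- sum(called & y)
    fp <- sum(called & !y)
    precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
    recall <- tp / n_pos
    area <- area + if (integration == "step") {
      (recall - prev_recall) * precision
    } else {
      (recall - prev_recall) * (precision + prev_precision) / 2
    }
    prev_recall <- recall
    prev_precision <- precision
  }
  area
}

#' Score one submission on every task
#'
#' Computes the MCC (confidences binarised at `threshold`) and the AUPR
#' for each task of the submission.
#'
#' @param sub A `submission`.
#' @param gold A `gold_standard`.
#' @param tasks Task list; defaults to the four challenge tasks.
#' @param grid AUPR threshold grid (see [aupr()]).
#' @param threshold Binarisation threshold for the MCC.
#' @return Tibble with one row per task: `submission_id`, `team_id`,
#'   `sub_challenge`, `data_type`, `task`, `mcc`, `aupr`.
#' @export
score_submission <- function(sub, gold, tasks = challenge_tasks(),
                             grid = "challenge", threshold = 0.5) {
  stopifnot(inherits(sub, "submission"))
  validate_submission(sub, gold)
  tasks <- tasks[intersect(names(tasks), names(sub$confidences))]
  rows <- lapply(tasks, function(task) {
    p <- sub$confidences[[task$name]]
    m <- mcc(confusion(binarize(p, threshold), gold, task))
    a <- aupr(p, gold, task, grid = grid)
    tibble::tibble(task = task$name, mcc = m, aupr = a)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(submission_id = sub$submission_id, team_id = sub$team_id,
                  sub_challenge = sub$sub_challenge, data_type = sub$data_type,
                  .before = 1)
}

#' Score a list of submissions
#'
#' @param subs List of `submission` objects.
#' @inheritParams score_submission
#' @return Long tibble, one row per (submission, task).
#' @export
score_submissions <- function(subs, gold, tasks = challenge_tasks(),
                              grid = "challenge", threshold = 0.5) {
  dplyr::bind_rows(lapply(subs, score_submission, gold = gold, tasks = tasks,
                          grid = grid, threshold = threshold))
}
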