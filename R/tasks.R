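# Domain types: class vocabulary, binary tasks, gold standard, submissions.

#' Class label vocabulary
#'
#' The three diagnostic groups of the cohort: Crohn's disease (`CD`),
#' ulcerative colitis (`UC`) and subjects without inflammatory bowel
#' disease (`nonIBD`).
#'
#' @return Character vector of the three admissible labels.
#' @export
class_levels <- function() c("CD", "UC", "nonIBD")

#' Construct a binary classification task
#'
#' A task is defined by the set of diagnostic labels forming class 1 (the
#' "positive" class whose membership probability participants report) and
#' the disjoint set forming class 2.  Samples whose gold label belongs to
#' neither set are out of scope and ignored by all metrics.
#'
#' @param name Task identifier.
#' @param class1 Labels forming class 1.
#' @param class2 Labels forming class 2.
#' @return A `challenge_task` object.
#' @export
new_task <- function(name, class1, class2) {
  stopifnot(is.character(name), length(name) == 1L)
  bad <- setdiff(c(class1, class2), class_levels())
  if (length(bad) > 0) {
    stop("unknown label(s) in task definition: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(class1, class2)) > 0) {
    stop("class1 and class2 must be disjoint", call. = FALSE)
  }
  structure(list(name = name, class1 = class1, class2 = class2),
            class = "challenge_task")
}

#' The four binary classification tasks of the challenge
#'
#' Fixed task set: IBD (CD or UC) versus nonIBD, CD versus nonIBD,
#' UC versus nonIBD, and the UC-versus-CD discrimination within IBD
#' (named `CDvsUC`; UC is class 1, CD class 2).  Task definitions are
#' constants so that the weighted-sum-of-ranks semantics stay stable.
#'
#' @return Named list of four `challenge_task` objects.
#' @export
challenge_tasks <- function() {
  list(
    IBDvsNonIBD = new_task("IBDvsNonIBD", c("CD", "UC"), "nonIBD"),
    CDvsNonIBD  = new_task("CDvsNonIBD", "CD", "nonIBD"),
    UCvsNonIBD  = new_task("UCvsNonIBD", "UC", "nonIBD"),
    CDvsUC      = new_task("CDvsUC", "UC", "CD")
  )
}

#' @export
print.challenge_task <- function(x, ...) {
  cat(sprintf("<task %s: {%s} (class 1) vs {%s} (class 2)>\n", x$name,
              paste(x$class1, collapse = ","), paste(x$class2, collapse = ",")))
  invisible(x)
}

task_names <- function() names(challenge_tasks())

#' Construct a gold standard
#'
#' @param labels Named character vector (names are sample identifiers) or a
#'   data frame with columns `sample_id` and `label`.
#' @return A `gold_standard` tibble with columns `sample_id`, `label`.
#' @export
gold_standard <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "label") %in% names(labels)))
    df <- tibble::tibble(sample_id = as.character(labels$sample_id),
                         label = as.character(labels$label))
  } else {
    if (is.null(names(labels))) stop("labels must be named by sample_id", call. = FALSE)
    df <- tibble::tibble(sample_id = names(labels), label = as.character(labels))
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$label), class_levels())
  if (length(bad) > 0) {
    stop("unknown label: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("gold_standard", class(df))
  df
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold standard: %d samples (%s)>\n", nrow(x),
              paste(sprintf("%s=%d", class_levels(),
                            vapply(class_levels(), function(l) sum(x$label == l), 0L)),
                    collapse = ", ")))
  invisible(x)
}

gold_label_vector <- function(gold) {
  stats::setNames(gold$label, gold$sample_id)
}

#' Gold class membership for a task
#'
#' Maps each gold-standard sample to 1 (class 1), 2 (class 2) or `NA`
#' (out of the task's scope).
#'
#' @param gold A `gold_standard`.
#' @param task A `challenge_task`.
#' @return Named integer vector over all gold samples.
#' @export
gold_classes <- function(gold, task) {
  stopifnot(inherits(gold, "gold_standard"), inherits(task, "challenge_task"))
  cls <- ifelse(gold$label %in% task$class1, 1L,
                ifelse(gold$label %in% task$class2, 2L, NA_integer_))
  stats::setNames(cls, gold$sample_id)
}

#' Construct a participant submission
#'
#' A submission carries one confidence vector per task: for every sample
#' the estimated probability `P1` in `[0, 1]` that the sample belongs to
#' class 1 of that task.
#'
#' @param submission_id Unique identifier.
#' @param confidences Named list, one element per task name, each a named
#'   numeric vector `sample_id -> P1`.
#' @param team_id Team identifier (defaults to the submission id).
#' @param sub_challenge `"SC1"` (raw-read based) or `"SC2"` (profile based).
#' @param data_type `"raw"`, `"taxonomy"` or `"function"`.
#' @param method_tags Named character vector, typically with entries
#'   `feature_selection` and `classifier`.
#' @param feature_importances Optional data frame with columns
#'   `feature_id`, `importance` (descending importance = better rank).
#' @return A `submission` object.
#' @export
submission <- function(submission_id, confidences, team_id = submission_id,
                       sub_challenge = c("SC1", "SC2"),
                       data_type = c("raw", "taxonomy", "function"),
                       method_tags = c(feature_selection = "unknown",
                                       classifier = "unknown"),
                       feature_importances = NULL) {
  sub_challenge <- match.arg(sub_challenge)
  data_type <- match.arg(data_type)
  stopifnot(is.list(confidences), !is.null(names(confidences)))
  unknown <- setdiff(names(confidences), task_names())
  if (length(unknown) > 0) {
    stop("unknown task(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (tk in names(confidences)) {
    p <- confidences[[tk]]
    if (is.null(names(p))) stop("confidences for ", tk, " must be named by sample_id",
                                call. = FALSE)
    check_confidence_range(p, context = tk)
  }
  if (!is.null(feature_importances)) {
    stopifnot(is.data.frame(feature_importances),
              all(c("feature_id", "importance") %in% names(feature_importances)))
    feature_importances <- tibble::as_tibble(feature_importances)
  }
  structure(list(submission_id = submission_id, team_id = team_id,
                 sub_challenge = sub_challenge, data_type = data_type,
                 method_tags = method_tags, confidences = confidences,
                 feature_importances = feature_importances),
            class = "submission")
}

check_confidence_range <- function(p, context = "confidences") {
  if (!is.numeric(p) || anyNA(p)) {
    stop("non-numeric or missing confidence value in ", context, call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    bad <- names(p)[which(p < 0 | p > 1)[1]]
    stop(sprintf("confidence outside [0,1] in %s (sample %s)", context, bad),
         call. = FALSE)
  }
  invisible(p)
}

#' Validate a submission against a gold standard
#'
#' Checks that every task's confidence map covers every gold-standard
#' sample; missing samples are an error.
#'
#' @param sub A `submission`.
#' @param gold A `gold_standard`.
#' @return The submission, invisibly, if valid.
#' @export
validate_submission <- function(sub, gold) {
  stopifnot(inherits(sub, "submission"), inherits(gold, "gold_standard"))
  for (tk in names(sub$confidences)) {
    missing <- setdiff(gold$sample_id, names(sub$confidences[[tk]]))
    if (length(missing) > 0) {
      stop(sprintf("submission %s, task %s: missing gold sample(s) %s",
                   sub$submission_id, tk, paste(missing, collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(sub)
}

#' @export
print.submission <- function(x, ...) {
  cat(sprintf("<submission %s (%s, %s, team %s): %d task(s), %d samples>\n",
              x$submission_id, x$sub_challenge, x$data_type, x$team_id,
              length(x$confidences),
              if (length(x$confidences)) length(x$confidences[[1]]) else 0L))
  invisible(x)
}
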