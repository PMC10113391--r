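# Consensus feature signatures from the best submissions' importance
# lists, and log2 fold-change profiles of signature features.

#' Select the top submissions for consensus building
#'
#' For one data type, ranks eligible submissions by the metric-averaged
#' rank (`R_problem`) on the IBD-versus-nonIBD task and returns the best
#' `n`.  Submissions whose confidence vectors exactly duplicate another's
#' (identical absolute values on every task) are collapsed to one
#' representative before the cut; a tie at the cut is broken by submission
#' id.
#'
#' @param subs List of `submission` objects of one data type.
#' @param scores Score tibble covering these submissions (floored scores
#'   are used when present, raw otherwise).
#' @param task Task used for ranking (default `IBDvsNonIBD`).
#' @param n Number of submissions to select (default 10).
#' @return List of `n` submissions, best first.
#' @export
select_top10 <- function(subs, scores, task = "IBDvsNonIBD", n = 10) {
  ids <- vapply(subs, function(s) s$submission_id, character(1))
  conf_key <- vapply(subs, function(s) {
    paste(vapply(names(s$confidences), function(tk) {
      p <- s$confidences[[tk]]
      paste(signif(p[sort(names(p))], 12), collapse = ",")
    }, character(1)), collapse = "|")
  }, character(1))
  rep_ids <- tapply(ids, conf_key, function(g) sort(g)[1])
  eligible <- ids %in% rep_ids
  if (sum(eligible) < n) {
    stop(sprintf("only %d eligible submissions after duplicate exclusion, need %d",
                 sum(eligible), n), call. = FALSE)
  }
  mcol <- if ("mcc_floored" %in% names(scores)) "mcc_floored" else "mcc"
  acol <- if ("aupr_floored" %in% names(scores)) "aupr_floored" else "aupr"
  tab <- scores[scores$task == task & scores$submission_id %in% ids[eligible], ]
  if (!setequal(tab$submission_id, ids[eligible])) {
    stop("score table does not cover all eligible submissions", call. = FALSE)
  }
  r <- aggregate_metric_ranks(rank_scores(tab[[acol]]), rank_scores(tab[[mcol]]))
  ord <- order(r, tab$submission_id)
  top_ids <- tab$submission_id[ord][seq_len(n)]
  subs[match(top_ids, ids)]
}

#' Consensus ordering of features across importance lists
#'
#' Within each submission, features are ranked by descending importance.
#' The global consensus order sorts by occurrence count (in how many lists
#' the feature appears, descending), then by the average within-list rank
#' over the lists containing the feature (ascending), then by feature id.
#' The alternative `"avg_rank"` method sorts purely by average rank, with
#' features absent from a list penalised with rank `length(list) + 1`.
#'
#' @param signatures List of feature-importance data frames
#'   (`feature_id`, `importance`), or of `submission`s carrying them.
#' @param method `"occurrence"` (default) or `"avg_rank"`.
#' @return A `consensus_signature` tibble: `feature_id`, `occurrence`,
#'   `avg_rank`, sorted in consensus order.
#' @export
consensus_order <- function(signatures, method = c("occurrence", "avg_rank")) {
  method <- match.arg(method)
  stopifnot(length(signatures) >= 1)
  lists <- lapply(signatures, function(s) {
    fi <- if (inherits(s, "submission")) s$feature_importances else s
    if (is.null(fi) || nrow(fi) == 0) stop("empty feature-importance list", call. = FALSE)
    fi <- tibble::as_tibble(fi)
    miss <- is.na(fi$importance)
    # a feature listed without an importance value is appended at the tail
    r <- numeric(nrow(fi))
    r[!miss] <- rank(-fi$importance[!miss], ties.method = "average")
    r[miss] <- nrow(fi)
    tibble::tibble(feature_id = as.character(fi$feature_id), r = r)
  })
  all_feats <- sort(unique(unlist(lapply(lists, function(l) l$feature_id))))
  occ <- avg <- pen <- stats::setNames(numeric(length(all_feats)), all_feats)
  for (l in lists) {
    occ[l$feature_id] <- occ[l$feature_id] + 1
    avg[l$feature_id] <- avg[l$feature_id] + l$r
    absent <- setdiff(all_feats, l$feature_id)
    pen[absent] <- pen[absent] + nrow(l) + 1
  }
  avg_rank <- avg / occ
  penalised <- (avg + pen) / length(lists)
  out <- tibble::tibble(feature_id = all_feats, occurrence = as.integer(occ),
                        avg_rank = unname(avg_rank),
                        penalised_rank = unname(penalised))
  ord <- if (method == "occurrence") {
    order(-out$occurrence, out$avg_rank, out$feature_id)
  } else {
    order(out$penalised_rank, out$feature_id)
  }
  out <- out[ord, ]
  class(out) <- c("consensus_signature", class(out))
  out
}

#' Build size-graded consensus signatures
#'
#' Takes the top-`k` prefix of the consensus order for every size `k` in
#' the grid.  The default grid, 4 to 200, yields 197 nested signatures.
#'
#' @param consensus A `consensus_signature` from [consensus_order()].
#' @param sizes Integer vector of signature sizes (default `4:200`).
#' @return Named list of feature-id vectors, one per size.
#' @export
build_signatures <- function(consensus, sizes = 4:200) {
  stopifnot(inherits(consensus, "consensus_signature"))
  sizes <- as.integer(sizes)
  if (max(sizes) > nrow(consensus)) {
    stop(sprintf("requested size %d exceeds the %d available features",
                 max(sizes), nrow(consensus)), call. = FALSE)
  }
  out <- lapply(sizes, function(k) consensus$feature_id[seq_len(k)])
  names(out) <- as.character(sizes)
  out
}

#' Log2 fold-change profile of signature features
#'
#' For every signature feature and sample:
#' `log2((a + eps) / (mean_s(a) + eps))`, the per-sample abundance
#' relative to the feature's average across all samples.  The pseudo-count
#' `eps` defaults to half the smallest non-zero abundance of the matrix,
#' which maps all-zero features to a flat zero profile instead of NaN.
#'
#' @param signature Character vector of feature ids.
#' @param x An `abundance_matrix`.
#' @param eps Pseudo-count; default half the smallest non-zero abundance.
#' @return Numeric matrix, features by samples.
#' @export
log2fc_profile <- function(signature, x, eps = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  missing <- setdiff(signature, rownames(x$abundance))
  if (length(missing) > 0) {
    stop("feature(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- x$abundance[signature, , drop = FALSE]
  if (is.null(eps)) {
    nz <- x$abundance[x$abundance > 0]
    eps <- if (length(nz) > 0) min(nz) / 2 else 1
  }
  log2((m + eps) / (rowMeans(m) + eps))
}
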