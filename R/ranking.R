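# Rank aggregation: per-metric ranks, per-task rank averaging, the
# weighted sum of ranks (WSR) and the leaderboard.

#' Rank scores, best first, with average ties
#'
#' The highest score receives the lowest rank; tied values receive the
#' average of the ranks they span.
#'
#' @param values Numeric vector of scores.
#' @return Numeric vector of ranks.
#' @export
rank_scores <- function(values) {
  stopifnot(length(values) >= 1)
  rank(-values, ties.method = "average")
}

#' Average the AUPR and MCC ranks for one task
#'
#' `R_problem = (R_aupr + R_mcc) / 2`.
#'
#' @param r_aupr,r_mcc Per-metric ranks (vectorised).
#' @return The per-task aggregated rank.
#' @export
aggregate_metric_ranks <- function(r_aupr, r_mcc) (r_aupr + r_mcc) / 2

#' Weighted sum of ranks for one data type
#'
#' The CD-versus-UC problem, the hardest of the four, carries double
#' weight: `WSR = R_IBD + R_CD + R_UC + 2 * R_CDvsUC`.
#'
#' @param r_ibd,r_cd,r_uc,r_cduc Per-task aggregated ranks (vectorised).
#' @return The weighted sum of ranks.
#' @export
wsr_sc1 <- function(r_ibd, r_cd, r_uc, r_cduc) r_ibd + r_cd + r_uc + 2 * r_cduc

#' Weighted sum of ranks across the two profile types
#'
#' The taxonomy-based and function-based components are averaged:
#' `WSR = (WSR_taxonomy + WSR_function) / 2`.
#'
#' @param tax_ranks,fun_ranks Length-4 rank vectors (IBD, CD, UC, CDvsUC
#'   order) or matrices with 4 columns.
#' @return The averaged weighted sum of ranks.
#' @export
wsr_sc2 <- function(tax_ranks, fun_ranks) {
  one <- function(r) {
    if (is.matrix(r)) wsr_sc1(r[, 1], r[, 2], r[, 3], r[, 4])
    else wsr_sc1(r[1], r[2], r[3], r[4])
  }
  (one(tax_ranks) + one(fun_ranks)) / 2
}

#' Build the leaderboard from a floored score table
#'
#' Ranks are computed on floored scores within each (sub-challenge,
#' data type, task, metric) column, averaged per task, combined into the
#' weighted sum of ranks (averaging the taxonomy and function components
#' for profile-based submissions) and sorted ascending: the lowest WSR is
#' the best submission.  Flooring before ranking makes every
#' non-significant submission tie on that column.
#'
#' @param scores Score tibble carrying `mcc_floored` and `aupr_floored`
#'   (see [add_significance()]); raw `mcc`/`aupr` may be used by setting
#'   `use_floored = FALSE`.
#' @param use_floored Rank floored (default) or raw scores.
#' @return Tibble with one row per submission: `submission_id`, `team_id`,
#'   `sub_challenge`, `wsr`, `position` (1 = best; ties share the minimum
#'   position).  The per-(data type, task) aggregated ranks are attached
#'   as the `"rank_table"` attribute.
#' @export
build_leaderboard <- function(scores, use_floored = TRUE) {
  mcol <- if (use_floored) "mcc_floored" else "mcc"
  acol <- if (use_floored) "aupr_floored" else "aupr"
  missing <- setdiff(c(mcol, acol), names(scores))
  if (length(missing) > 0) {
    stop("score table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gaps <- scores |>
    dplyr::count(.data$submission_id, .data$data_type) |>
    dplyr::filter(.data$n < length(task_names()))
  if (nrow(gaps) > 0) {
    stop("incomplete task coverage for submission(s): ",
         paste(unique(gaps$submission_id), collapse = ", "), call. = FALSE)
  }
  ranked <- scores |>
    dplyr::group_by(.data$sub_challenge, .data$data_type, .data$task) |>
    dplyr::mutate(r_mcc = rank_scores(.data[[mcol]]),
                  r_aupr = rank_scores(.data[[acol]]),
                  r_problem = aggregate_metric_ranks(.data$r_aupr, .data$r_mcc)) |>
    dplyr::ungroup()
  components <- ranked |>
    tidyr::pivot_wider(id_cols = c("submission_id", "team_id", "sub_challenge",
                                   "data_type"),
                       names_from = "task", values_from = "r_problem") |>
    dplyr::mutate(wsr_component = wsr_sc1(.data$IBDvsNonIBD, .data$CDvsNonIBD,
                                          .data$UCvsNonIBD, .data$CDvsUC))
  sc2 <- components |> dplyr::filter(.data$sub_challenge == "SC2")
  if (nrow(sc2) > 0) {
    bad <- sc2 |>
      dplyr::count(.data$submission_id) |>
      dplyr::filter(.data$n != 2)
    if (nrow(bad) > 0) {
      stop("SC2 submission(s) lacking one data type: ",
           paste(bad$submission_id, collapse = ", "), call. = FALSE)
    }
  }
  board <- components |>
    dplyr::group_by(.data$submission_id, .data$team_id, .data$sub_challenge) |>
    dplyr::summarise(wsr = mean(.data$wsr_component), .groups = "drop") |>
    dplyr::group_by(.data$sub_challenge) |>
    dplyr::mutate(position = rank(.data$wsr, ties.method = "min")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sub_challenge, .data$wsr, .data$submission_id)
  attr(board, "rank_table") <- ranked
  board
}

#' Per-(task, metric) rank table behind a leaderboard
#'
#' @param board A leaderboard from [build_leaderboard()].
#' @return The long rank tibble.
#' @export
rank_table <- function(board) attr(board, "rank_table")

#' Team-level view of a leaderboard
#'
#' Awards go to teams; a team's entry is its best (lowest-WSR) submission.
#'
#' @param board A leaderboard from [build_leaderboard()].
#' @return Tibble with one row per team, sorted by WSR.
#' @export
team_leaderboard <- function(board) {
  board |>
    dplyr::group_by(.data$sub_challenge, .data$team_id) |>
    dplyr::slice_min(.data$wsr, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sub_challenge, .data$wsr, .data$submission_id)
}
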