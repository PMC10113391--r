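# Wisdom-of-crowd aggregation: filtering, averaging, subset ensembles,
# robustness, data-type pairing.

make_tagged_sub <- function(gold, id, team, fs, cl, quality = 0.6, seed = 1) {
  generate_submission(quality, gold, seed = seed, submission_id = id,
                      team_id = team,
                      method_tags = c(feature_selection = fs, classifier = cl))
}

test_that("one representative per method group, inverted excluded", {
  gold <- tiny_gold(6, 5, 7)
  subs <- list(
    make_tagged_sub(gold, "a1", "T1", "lasso", "RF", seed = 1),
    make_tagged_sub(gold, "a2", "T1", "lasso", "RF", seed = 2),
    make_tagged_sub(gold, "b1", "T1", "mRMR", "SVM", seed = 3),
    make_tagged_sub(gold, "b2", "T1", "mRMR", "SVM", seed = 4),
    make_tagged_sub(gold, "c1", "T2", "lasso", "RF", seed = 5),
    make_tagged_sub(gold, "c2", "T2", "lasso", "RF", seed = 6))
  kept <- filter_for_aggregation(subs, seed = 10)
  expect_length(kept, 3)
  teams <- vapply(kept, function(s) paste(s$team_id,
                                          s$method_tags[["feature_selection"]]),
                  character(1))
  expect_setequal(teams, c("T1 lasso", "T1 mRMR", "T2 lasso"))

  kept2 <- filter_for_aggregation(subs, inverted_ids = c("a1", "a2"), seed = 10)
  ids2 <- vapply(kept2, function(s) s$submission_id, character(1))
  expect_false(any(c("a1", "a2") %in% ids2))
  expect_lte(length(kept2), 3)

  again <- filter_for_aggregation(subs, seed = 10)
  expect_equal(vapply(kept, function(s) s$submission_id, character(1)),
               vapply(again, function(s) s$submission_id, character(1)))
})

test_that("aggregation averages confidences and keeps the bounds", {
  gold <- tiny_gold(4, 3, 5)
  a <- gold_echo_submission(gold, 0.6, id = "a")   # P1 = 0.8 for class 1
  b <- gold_echo_submission(gold, 0.6, id = "b",
                            flip_samples = gold$sample_id)  # P1 = 0.2
  agg <- aggregate_submissions(list(a, b))
  expect_true(all(vapply(agg$confidences, function(p) all(abs(p - 0.5) < 1e-12),
                         logical(1))))

  solo <- aggregate_submissions(list(a))
  for (tk in names(a$confidences)) {
    expect_equal(solo$confidences[[tk]][names(a$confidences[[tk]])],
                 a$confidences[[tk]])
  }

  set.seed(6)
  members <- lapply(1:5, function(i) generate_submission(
    0.5, gold, seed = i, submission_id = paste0("m", i)))
  agg2 <- aggregate_submissions(members)
  for (tk in names(agg2$confidences)) {
    stack <- sapply(members, function(s) s$confidences[[tk]][gold$sample_id])
    expect_true(all(agg2$confidences[[tk]][gold$sample_id] >= apply(stack, 1, min) - 1e-12))
    expect_true(all(agg2$confidences[[tk]][gold$sample_id] <= apply(stack, 1, max) + 1e-12))
    expect_equal(unname(agg2$confidences[[tk]][gold$sample_id]),
                 unname(rowMeans(stack)))
  }

  short <- a
  short$confidences$CDvsUC <- short$confidences$CDvsUC[-1]
  expect_error(aggregate_submissions(list(a, short)), "coverage mismatch")
})

test_that("subset sampling enumerates below the cap and caps above it", {
  gold <- tiny_gold(6, 5, 7)
  pool <- lapply(1:5, function(i) generate_submission(
    0.5, gold, seed = i, submission_id = paste0("p", i)))
  res <- random_subset_experiment(pool, sizes = 3, seed = 2, gold = gold)
  expect_equal(length(unique(res$combo)), choose(5, 3))

  pool10 <- lapply(1:10, function(i) generate_submission(
    0.5, gold, seed = i, submission_id = paste0("q", i)))
  res2 <- random_subset_experiment(pool10, sizes = 4, max_combos = 50,
                                   seed = 2, gold = gold)
  expect_equal(length(unique(res2$combo)), 50)

  res3 <- random_subset_experiment(pool, sizes = 5, seed = 2, gold = gold)
  expect_equal(length(unique(res3$combo)), 1)  # all-member aggregate

  expect_error(random_subset_experiment(pool, sizes = 6, seed = 2, gold = gold),
               "subset size exceeds")
})

test_that("aggregates of a few calibrated members beat the mean individual", {
  gold <- tiny_gold(35, 25, 45)
  pool <- lapply(1:12, function(i) generate_submission(
    0.35, gold, seed = 100 + i, submission_id = sprintf("w%02d", i)))
  ind <- score_submissions(pool, gold)
  ind_mean <- mean(ind$mcc[ind$task == "IBDvsNonIBD"])
  res <- random_subset_experiment(pool, sizes = 3, max_combos = 60, seed = 5,
                                  gold = gold)
  agg_mean <- mean(res$mcc[res$task == "IBDvsNonIBD"])
  expect_gt(agg_mean, ind_mean)
})

test_that("aggregate quality is non-decreasing in ensemble size on average", {
  gold <- tiny_gold(35, 25, 45)
  pool <- lapply(1:15, function(i) generate_submission(
    0.3, gold, seed = 200 + i, submission_id = sprintf("e%02d", i)))
  res <- random_subset_experiment(pool, sizes = c(3, 7, 15), max_combos = 40,
                                  seed = 8, gold = gold)
  ib <- res[res$task == "IBDvsNonIBD", ]
  means <- tapply(ib$mcc, ib$size, mean)
  expect_gt(means[["7"]], means[["3"]] - 0.02)
  expect_gt(means[["15"]], means[["3"]])
})

test_that("robustness trajectories have the documented shape", {
  gold <- tiny_gold(12, 9, 14)
  pool <- lapply(1:10, function(i) generate_submission(
    seq(0.1, 0.9, length.out = 10)[i], gold, seed = 300 + i,
    submission_id = sprintf("r%02d", i)))
  rob <- robustness_experiment(pool, gold)
  expect_equal(nrow(rob), 8)
  expect_equal(rob$step[rob$direction == "worst"], 0:3)
  expect_equal(rob$n_members, rep(4:7, 2))
  expect_error(robustness_experiment(pool[1:5], gold), "at least 7")
})

test_that("adding strong members helps more than adding noise", {
  gold <- tiny_gold(35, 25, 45)
  # qualities low enough that aggregates stay off the metric ceiling
  pool <- c(
    lapply(1:3, function(i) generate_submission(
      0.5, gold, seed = 400 + i, concentration = 3,
      submission_id = sprintf("best%d", i))),
    lapply(1:6, function(i) generate_submission(
      0.15, gold, seed = 410 + i, concentration = 3,
      submission_id = sprintf("mid%d", i))),
    lapply(1:3, function(i) generate_submission(
      0, gold, seed = 420 + i, concentration = 3,
      submission_id = sprintf("rand%d", i))))
  rob <- robustness_experiment(pool, gold)
  best <- rob[rob$direction == "best", ]
  worst <- rob[rob$direction == "worst", ]
  expect_gt(best$aupr[best$step == 3], best$aupr[best$step == 0])
  # uniform-noise members leave the AUPR within a noise band
  expect_lt(abs(worst$aupr[worst$step == 3] - worst$aupr[worst$step == 0]), 0.15)
})

test_that("pairing taxonomy and function predictions behaves as documented", {
  gold <- tiny_gold(12, 9, 14)
  tax <- lapply(1:6, function(i) {
    s <- generate_submission(0.5, gold, seed = 500 + i,
                             submission_id = sprintf("pair%d", i))
    s$data_type <- "taxonomy"; s
  })
  fun_same <- lapply(tax, function(s) { f <- s; f$data_type <- "function"; f })
  same <- pair_datatype_aggregation(tax, fun_same, gold)
  expect_equal(same$records$score_aggregate, same$records$score_taxonomy)
  expect_true(all(same$tests$p_value > 0.99))

  # a much stronger function member drags the aggregate below itself
  weak_tax <- generate_submission(0.1, gold, seed = 600, concentration = 3,
                                  submission_id = "p")
  strong_fun <- generate_submission(0.9, gold, seed = 601, concentration = 3,
                                    submission_id = "p")
  res <- pair_datatype_aggregation(list(weak_tax), list(strong_fun), gold,
                                   metric = "mcc")
  expect_lt(res$records$score_aggregate, res$records$score_function)

  expect_error(pair_datatype_aggregation(tax[1:2], fun_same[3:4], gold),
               "unmatched pair")
})
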