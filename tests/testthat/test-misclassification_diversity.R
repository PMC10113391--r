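# Deduplication, misclassification rates, Shannon diversity and the
# group-wise statistics behind the rate-versus-diversity analysis.

test_that("binarized-identical submissions collapse to one representative", {
  gold <- tiny_gold(4, 3, 5)
  a <- gold_echo_submission(gold, 0.8, id = "subA")
  b <- gold_echo_submission(gold, 0.4, id = "subB")     # same calls as A
  c_ <- gold_echo_submission(gold, 0.8, id = "subC", flip_samples = "s01")
  d <- gold_echo_submission(gold, 0.2, id = "subD", flip_samples = "s01")
  e <- gold_echo_submission(gold, 0.8, id = "subE", flip_samples = c("s01", "s05"))
  ret <- dedup_binarized(list(a, b, c_, d, e))
  ids <- vapply(ret, function(s) s$submission_id, character(1))
  expect_setequal(ids, c("subA", "subC", "subE"))  # lexicographic reps

  all_distinct <- list(a, c_, e)
  expect_length(dedup_binarized(all_distinct), 3)
})

test_that("deduplication is idempotent and rates ignore duplicates", {
  gold <- tiny_gold(4, 3, 5)
  subs <- list(gold_echo_submission(gold, 0.8, id = "a"),
               gold_echo_submission(gold, 0.8, id = "b", flip_samples = "s01"),
               gold_echo_submission(gold, 0.3, id = "c", flip_samples = "s01"))
  once <- dedup_binarized(subs)
  twice <- dedup_binarized(once)
  expect_equal(vapply(once, function(s) s$submission_id, character(1)),
               vapply(twice, function(s) s$submission_id, character(1)))

  r1 <- misclassification_rates(dedup_binarized(subs), gold)
  dup <- gold_echo_submission(gold, 0.55, id = "a2")  # binarized copy of "a"
  r2 <- misclassification_rates(dedup_binarized(c(subs, list(dup))), gold)
  expect_equal(r1$rate, r2$rate)
})

test_that("per-sample misclassification rate is the error fraction", {
  gold <- tiny_gold(4, 3, 5)
  task <- challenge_tasks()$IBDvsNonIBD
  # 12 submissions, 3 of which flip sample s01
  subs <- c(
    lapply(1:3, function(i) gold_echo_submission(
      gold, 0.2 + 0.05 * i, id = sprintf("bad%d", i), flip_samples = "s01")),
    lapply(1:9, function(i) gold_echo_submission(
      gold, 0.2 + 0.05 * i, id = sprintf("good%d", i)))
  )
  expect_equal(misclassification_rate("s01", task, subs, gold), 0.25)
  expect_equal(misclassification_rate("s02", task, subs, gold), 0)
  expect_error(misclassification_rate("nope", task, subs, gold), "out of scope")
  # a UC sample is out of scope for CD-vs-nonIBD
  expect_error(misclassification_rate("s05", challenge_tasks()$CDvsNonIBD,
                                      subs, gold), "out of scope")
})

test_that("Shannon index matches hand values and vegan", {
  expect_equal(shannon(c(25, 25, 25, 25)), log(4))
  expect_equal(shannon(c(0, 0, 7, 0)), 0)
  expect_equal(shannon(c(50, 25, 25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "non-negative")

  skip_if_not_installed("vegan")
  set.seed(4)
  for (i in 1:20) {
    v <- rexp(sample(3:40, 1))
    expect_equal(shannon(v), unname(vegan::diversity(v, index = "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("Shannon is scale-invariant and bounded by log richness", {
  set.seed(11)
  for (i in 1:50) {
    v <- c(rexp(sample(2:20, 1)), rep(0, sample(0:5, 1)))
    expect_equal(shannon(v), shannon(v * runif(1, 0.1, 50)), tolerance = 1e-12)
    expect_lte(shannon(v), log(sum(v > 0)) + 1e-12)
  }
  expect_equal(shannon(rep(3, 7)), log(7))
})

test_that("group rate comparison behaves as a Mann-Whitney U test", {
  same <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_gt(group_rate_test(same, same)$p_value, 0.9)
  sep <- group_rate_test(seq(0.6, 0.9, length.out = 10),
                         seq(0.1, 0.4, length.out = 10))
  expect_true(sep$statistic %in% c(0, 100))
  expect_lt(sep$p_value, 0.001)
  expect_error(group_rate_test(numeric(0), same), "non-empty")

  # constructed stochastic dominance is detected
  set.seed(2)
  hi <- rbeta(40, 6, 4)
  lo <- rbeta(40, 4, 6)
  expect_lt(group_rate_test(hi, lo)$p_value, 0.05)
})

test_that("rate-diversity correlation handles monotone and degenerate input", {
  x <- 1:10
  up <- rate_diversity_correlation(x / 10, x + runif(10, 0, 1e-6))
  expect_equal(unname(up$estimate), 1)
  down <- rate_diversity_correlation(x / 10, rev(x) + runif(10, 0, 1e-6))
  expect_equal(unname(down$estimate), -1)
  expect_error(rate_diversity_correlation(rep(0.5, 5), 1:5), "constant")
  expect_error(rate_diversity_correlation(1:2 / 10, 1:2), "at least 3")
  p <- rate_diversity_correlation((1:20) / 20, (1:20) + rnorm(20, 0, 2),
                                  method = "pearson")
  expect_true(is.finite(p$estimate))
})

test_that("the misclassification report joins rates with diversity", {
  cfg <- scenario_config(n_samples = 40, n_taxa = 60, n_pathways = 40,
                         n_informative = 8, n_sc1 = 3, n_sc2_unique = 6,
                         n_duplicate_pairs = 2, seed = 21)
  sim <- simulate_challenge(cfg)
  tax_subs <- Filter(function(s) s$data_type == "taxonomy", sim$sc2)
  rep <- misclassification_report(tax_subs, sim$gold, taxonomy = sim$taxonomy,
                                  functional = sim$functional)
  expect_true(all(c("rate", "group", "shannon_taxonomy", "shannon_function")
                  %in% names(rep)))
  expect_true(all(rep$rate >= 0 & rep$rate <= 1))
  expect_equal(unique(rep$n_submissions), 6)   # duplicates removed
  ib <- rep[rep$task == "IBDvsNonIBD", ]
  expect_equal(nrow(ib), 40)
  expect_true(all(ib$shannon_taxonomy > 0))
})
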