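# The synthetic challenge generator: cohort, abundance structure,
# submissions of controllable quality.

test_that("cohort generation is seeded multinomial over the proportions", {
  cfg <- scenario_config(seed = 31)
  gold <- generate_cohort(cfg)
  expect_equal(nrow(gold), 105)
  counts <- table(gold$label)
  expect_true(all(counts >= 10))  # far inside the multinomial range
  gold2 <- generate_cohort(cfg)
  expect_equal(gold$label, gold2$label)
  gold3 <- generate_cohort(scenario_config(seed = 32))
  expect_false(identical(gold$label, gold3$label))
  expect_true(all(c("u", "difficulty") %in% names(attr(gold, "latent"))))
})

test_that("taxonomy abundances are percent-normalised and reproducible", {
  cfg <- scenario_config(n_samples = 30, n_taxa = 50, n_informative = 10,
                         seed = 7)
  gold <- generate_cohort(cfg)
  tax <- generate_abundance(cfg, gold, "taxonomy")
  expect_equal(unname(colSums(tax$abundance)), rep(100, 30), tolerance = 1e-9)
  expect_length(attr(tax, "informative"), 10)
  tax2 <- generate_abundance(cfg, gold, "taxonomy")
  expect_identical(tax$abundance, tax2$abundance)
  fun <- generate_abundance(cfg, gold, "function")
  expect_true(all(fun$abundance >= 0))
  expect_false(isTRUE(all.equal(unname(colSums(fun$abundance)), rep(100, 30))))
})

test_that("a positive diversity offset lowers IBD Shannon diversity", {
  cfg <- scenario_config(n_samples = 90, seed = 19, diversity_offset = 0.8)
  gold <- generate_cohort(cfg)
  tax <- generate_abundance(cfg, gold, "taxonomy")
  h <- sample_shannon(tax)
  ibd <- gold_label_vector(gold) != "nonIBD"
  t <- t.test(h[!ibd], h[ibd], alternative = "greater")
  expect_lt(t$p.value, 0.01)
})

test_that("zero effect size leaves features uninformative", {
  cfg <- scenario_config(n_samples = 60, n_taxa = 80, n_informative = 10,
                         effect_size = 0, diversity_offset = 0,
                         contamination = 0, seed = 23)
  gold <- generate_cohort(cfg)
  # the pathway matrix is not closed to a constant sum, so with all group
  # effects off its features carry no group signal at all
  fun <- generate_abundance(cfg, gold, "function")
  ibd <- gold_label_vector(gold) != "nonIBD"
  pvals <- apply(fun$abundance, 1, function(v) {
    suppressWarnings(wilcox.test(v[ibd], v[!ibd], exact = FALSE))$p.value
  })
  # p-values behave like a uniform sample: no excess of small values
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.35)
})

test_that("large effects on informative features are recovered by the pipeline", {
  cfg <- scenario_config(n_samples = 80, n_taxa = 150, n_informative = 20,
                         effect_size = 1.5, n_sc2_unique = 12,
                         n_duplicate_pairs = 0, inverted_fraction = 0,
                         quality_range = c(0.5, 0.9), seed = 29)
  sim <- simulate_challenge(cfg)
  tax_subs <- Filter(function(s) s$data_type == "taxonomy", sim$sc2)
  scores <- score_submissions(tax_subs, sim$gold)
  top <- select_top10(tax_subs, scores)
  co <- consensus_order(top)
  recovered <- sum(head(co$feature_id, 20) %in% sim$manifest$informative_taxa)
  expect_gte(recovered, 16)
})

test_that("submission quality sets the score and inversion flips it", {
  gold <- tiny_gold(35, 25, 45)
  perfect <- generate_submission(1, gold, seed = 1, submission_id = "perf")
  sc <- score_submission(perfect, gold)
  expect_equal(sc$mcc, rep(1, 4))
  expect_equal(sc$aupr, rep(1, 4))

  null_scores <- replicate(20, {
    s <- generate_submission(0, gold, seed = sample.int(1e6, 1),
                             submission_id = "r")
    score_submission(s, gold)$mcc[1]
  })
  expect_lt(abs(mean(null_scores)), 3 / sqrt(20 * 105))

  base <- generate_submission(0.9, gold, seed = 77, submission_id = "b")
  inv <- generate_submission(0.9, gold, seed = 77, submission_id = "i",
                             inverted = TRUE)
  sb <- score_submission(base, gold)
  si <- score_submission(inv, gold)
  expect_equal(si$mcc, -sb$mcc, tolerance = 1e-12)

  again <- generate_submission(0.9, gold, seed = 77, submission_id = "b")
  expect_identical(base$confidences, again$confidences)
})

test_that("mean confidence separation is monotone in quality", {
  gold <- tiny_gold(35, 25, 45)
  task <- challenge_tasks()$IBDvsNonIBD
  cls <- gold_classes(gold, task)
  sep <- vapply(c(0.2, 0.5, 0.8), function(q) {
    s <- generate_submission(q, gold, seed = 55, submission_id = "m")
    p <- s$confidences$IBDvsNonIBD
    mean(p[cls == 1]) - mean(p[cls == 2])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("the simulated challenge has the documented composition", {
  cfg <- scenario_config(seed = 43)
  sim <- simulate_challenge(cfg)
  expect_length(sim$sc1, 17)
  tax_subs <- Filter(function(s) s$data_type == "taxonomy", sim$sc2)
  fun_subs <- Filter(function(s) s$data_type == "function", sim$sc2)
  expect_length(tax_subs, 60)
  expect_length(fun_subs, 60)
  expect_length(sim$manifest$duplicate_pairs, 16)
  expect_true(all(vapply(tax_subs, function(s)
    !is.null(s$feature_importances), logical(1))))
  # every engineered duplicate binarizes identically to its source
  ids <- vapply(tax_subs, function(s) s$submission_id, character(1))
  for (pair in sim$manifest$duplicate_pairs) {
    p <- strsplit(pair, ":")[[1]]
    src <- tax_subs[[match(p[1], ids)]]
    dup <- tax_subs[[match(p[2], ids)]]
    for (tk in names(src$confidences)) {
      expect_equal(unname(binarize(src$confidences[[tk]])),
                   unname(binarize(dup$confidences[[tk]])))
      expect_false(identical(src$confidences[[tk]], dup$confidences[[tk]]))
    }
  }
})

test_that("a written scenario can be read back faithfully", {
  cfg <- scenario_config(n_samples = 15, n_taxa = 12, n_pathways = 8,
                         n_informative = 3, n_sc1 = 2, n_sc2_unique = 3,
                         n_duplicate_pairs = 1, seed = 3)
  sim <- simulate_challenge(cfg)
  d <- withr::local_tempdir()
  write_scenario(sim, d)
  gold <- read_gold_standard(file.path(d, "gold_standard.csv"))
  expect_equal(gold$label, sim$gold$label)
  tax <- read_abundance_matrix(file.path(d, "taxonomy.tsv"), "taxonomy",
                               file.path(d, "taxonomy_description.csv"))
  expect_equal(tax$abundance, sim$taxonomy$abundance, tolerance = 1e-8)
  subs <- list.files(file.path(d, "submissions"), pattern = "_taxonomy\\.csv$")
  expect_length(subs, 4)  # 3 unique + 1 duplicate
  back <- read_submission(file.path(d, "submissions", subs[1]), gold)
  expect_length(back$confidences, 4)
})
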