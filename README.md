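# crowdscore

Evaluation machinery for crowdsourced binary-classification challenges on
microbiome profiles, built for an inflammatory bowel disease (IBD)
diagnostic setting with three cohort groups (Crohn's disease `CD`,
ulcerative colitis `UC`, and `nonIBD` controls) and four fixed binary
tasks (`IBDvsNonIBD`, `CDvsNonIBD`, `UCvsNonIBD`, `CDvsUC`).

It is written for challenge organisers and method benchmarkers who need
the whole pipeline, not just a metric: scoring, significance against a
simulated null, rank aggregation into a leaderboard, and the post-hoc
analyses that make the scores interpretable.

## What it computes

* **Scoring** — per task, the Matthews correlation coefficient on
  confidences binarised at 0.5,

  `MCC = (tp·tn − fp·fn) / √((tp+fp)(tp+fn)(tn+fp)(tn+fn))`,

  and the area under the precision-recall curve built with a moving
  threshold from 1 down to 0.5 (a full-range mode equal to classical
  average precision is also provided).  Samples outside a task's two
  classes are ignored.
* **Significance** — per (task, metric), the empirical null of 10,000
  uniform random prediction sets; scores at or below the null's 95th
  percentile are *floored* to that threshold.
* **Leaderboard** — floored scores become ranks (average ties), metric
  ranks are averaged per task (`R_problem`), and tasks combine into the
  weighted sum of ranks `WSR = R_IBD + R_CD + R_UC + 2·R_CDvsUC`
  (averaged over the taxonomy and function components for profile-based
  submissions).  Lowest WSR wins.
* **Misclassification vs diversity** — per-sample misclassification
  rates over deduplicated submissions (binarized-identical copies are
  collapsed first), Shannon diversity `H' = −Σ pᵢ ln pᵢ`, Mann-Whitney
  group tests and Spearman rate-diversity correlations.
* **Consensus signatures** — occurrence-then-average-rank aggregation of
  the top-10 submissions' feature lists into 197 nested signatures
  (sizes 4–200), evaluated with a seven-classifier repeated stratified
  cross-validation harness (kNN, LDA, RF, linear SVM, PLS-DA, naive
  Bayes, XGBoost), plus log2 fold-change abundance profiles.
* **Wisdom of the crowd** — confidence-averaged aggregates over random
  member subsets (capped at 1,000 distinct combinations), robustness
  trajectories when re-adding the best/worst members, and
  taxonomy-function pairing with signed-rank tests.
* **Synthetic challenge generator** — a 105-sample cohort,
  group-structured taxonomy/pathway matrices with a diversity offset, and
  submissions of controllable quality (including engineered
  binarized-duplicate pairs and inverted submissions), so everything
  above runs end-to-end with known ground truth.

See `vignettes/challenge-evaluation.Rmd` for the full model description
and design rationale.

## Worked example

```r
library(crowdscore)

cfg    <- scenario_config(seed = 1)          # the default study scenario
sim    <- simulate_challenge(cfg)            # gold standard, matrices, submissions
nulls  <- build_null_set(sim$gold, n_draws = 2000, seed = 1)
scores <- add_significance(score_submissions(sim$sc2, sim$gold), nulls)
board  <- build_leaderboard(scores)
head(board, 5)
#> # A tibble: 5 × 5
#>   submission_id team_id sub_challenge   wsr position
#>   <chr>         <chr>   <chr>         <dbl>    <int>
#> 1 SC2_38        T10     SC2            92.6        1
#> 2 SC2_18        T11     SC2           107.         2
#> 3 SC2_25        T05     SC2           111.         3
#> 4 SC2_05        T08     SC2           112          4
#> 5 SC2_23        T05     SC2           117.         5
```

The WSR column is the weighted sum of ranks across the four tasks and
both data types — lower is better — and `position` is the leaderboard
placing after sorting.  The misclassification analysis on the same run:

```r
rep <- misclassification_report(
  Filter(function(s) s$data_type == "taxonomy", sim$sc2),
  sim$gold, taxonomy = sim$taxonomy)
ib <- subset(rep, task == "IBDvsNonIBD")
mean(ib$rate[ib$group == "IBD"])     #> 0.506
mean(ib$rate[ib$group == "nonIBD"])  #> 0.272
group_rate_test(ib$rate[ib$group == "IBD"], ib$rate[ib$group == "nonIBD"])
#> # A tibble: 1 × 2
#>   statistic  p_value
#>       <dbl>    <dbl>
#> 1      2332 1.25e-10
```

IBD samples are misclassified markedly more often than nonIBD samples
(Mann-Whitney U = 2332, p ≈ 1e-10), the pattern the scenario is built to
carry.

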