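---
title: "Scoring and post-hoc analysis of crowdsourced microbiome classification challenges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and post-hoc analysis of crowdsourced microbiome classification challenges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdscore)
```

# The evaluation problem

`crowdscore` implements the complete evaluation machinery of a
crowdsourced diagnostic challenge in which participants classify stool
metagenome samples from an inflammatory bowel disease (IBD) cohort.  The
cohort contains three diagnostic groups -- Crohn's disease (`CD`),
ulcerative colitis (`UC`) and subjects without IBD (`nonIBD`) -- and
every submission addresses four fixed binary tasks:

| task          | class 1    | class 2  |
|---------------|-----------|----------|
| `IBDvsNonIBD` | CD, UC    | nonIBD   |
| `CDvsNonIBD`  | CD        | nonIBD   |
| `UCvsNonIBD`  | UC        | nonIBD   |
| `CDvsUC`      | UC        | CD       |

For each task a submission supplies one confidence value $P_1 \in [0,1]$
per sample: the estimated probability that the sample belongs to class 1
(with $P_2 = 1 - P_1$).  Samples whose gold label lies outside a task's
two classes are ignored by every metric for that task.  Note the naming
convention of the fourth task: it is conventionally referred to as
"CD versus UC", but UC is its class 1.

# Scoring model

Two complementary metrics are computed per submission, task and data
type.

**MCC.** Confidences are binarised at a fixed threshold of 0.5 and the
Matthews correlation coefficient is computed from the resulting confusion
matrix:

$$\mathrm{MCC} = \frac{tp\,tn - fp\,fn}
{\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}.$$

When any marginal of the confusion matrix is zero the MCC is defined as
0; degenerate predictions occur routinely inside the random null, so the
convention is load-bearing.  A confidence exactly at the threshold is
assigned to class 2, so that a coin-flip value of exactly 0.5 does not
inflate positive calls.  The tie direction is configurable.

**AUPR.** The area under the precision-recall curve is built with a
moving threshold $t$ running from 1 down to 0.5 (all distinct confidence
values in $(0.5, 1]$ plus both endpoints); at each $t$ the prediction is
class 1 when $P_1 \ge t$.  The curve is integrated with the
right-continuous step rule of average precision: each recall increment
contributes the precision attained at that threshold.  Because the grid
stops at 0.5, recall need not reach 1 and the score is the partial area
over the explored recall range -- a submission whose confidences all sit
below 0.5 scores 0 even if its ranking is perfect.  A `grid = "full"`
mode extends the grid to $[0,1]$; in that mode the implementation is
exactly classical average precision, which the test suite verifies
against a brute-force oracle on every label pattern of a 12-sample
instance.

A documented ambiguity: the challenge's methods text mentions recall and
*specificity* when describing the AUPR construction.  Since the metric is
named precision-recall, this package implements precision-recall; the
restricted 1-to-0.5 grid is preserved as stated.  A trapezoidal
integration mode exists but is off by default, as the step rule is what
makes the full-range mode coincide with average precision.

# Significance against a random null

To decide whether a score beats chance, the package simulates the null
distribution of each (task, metric) pair: 10,000 prediction sets, each
assigning an independent uniform $[0,1]$ confidence to every sample, are
scored against the gold standard.  Scores strictly greater than the 95th
percentile of the null are significant; all other scores are *floored*,
i.e. replaced by the 95th-percentile value, before any ranking.  Flooring
makes every non-significant submission tie on that column, which is
exactly the intended semantics: differences below the noise floor carry
no evidence.

Numerical choices: the percentile uses linear interpolation between order
statistics (`quantile` type 7) by default, with a nearest-rank option,
since the original description does not pin the rule down; a score
exactly at the threshold counts as *not* better than random; one null per
(task, metric) is shared by all submissions because it depends only on
the gold standard; and per-(task, metric) child seeds are spawned
deterministically from one master seed so the whole pipeline is
bit-reproducible.

# Rank aggregation and the leaderboard

Within each (sub-challenge, data type, task, metric) column, floored
scores are converted to ranks (highest score, lowest rank; ties receive
the average of the spanned ranks).  Per task the two metric ranks are
averaged,

$$R_{problem} = \tfrac12\left(R^{AUPR}_{problem} + R^{MCC}_{problem}\right),$$

and per submission the four task ranks are combined into the weighted sum
of ranks, with double weight on the hardest task:

$$\mathrm{WSR} = R_{IBD} + R_{CD} + R_{UC} + 2\,R_{CDvsUC}.$$

Profile-based submissions carry a taxonomy-based and a function-based
prediction set; their WSR is the mean of the two components.  The
leaderboard sorts ascending by WSR (displayed ties broken by submission
id; WSR values themselves are reported untied), and team-level awarding
is a view that keeps each team's best submission.  Ranks are always
computed over all submissions of a sub-challenge.

# Misclassification and diversity

Per-sample misclassification rates are the fraction of submissions whose
binarised call differs from the gold label.  Before computing them,
submissions with identical binarised predictions across all four tasks
are collapsed to one representative (the lexicographically smallest
submission id -- a deterministic, seed-free choice), so that teams
uploading near-copies do not weight the rates.

Within-sample (alpha) diversity is the Shannon index
$H' = -\sum_i p_i \ln p_i$ over relative abundances; it is computed at
the Species level of the taxonomy matrix by default (the level is
configurable, as the level behind the original analysis is not stated).
Group comparisons of rates use two-sided Mann-Whitney U tests; the
rate-diversity association uses Spearman correlation by default (rates
are bounded proportions; Pearson is available by flag), with a
significance flag at $p < 0.05$.

# Consensus signatures and the classifier harness

For one data type, the ten best submissions on the IBD-versus-nonIBD
task (by $R_{problem}$, after collapsing submissions with exactly
duplicated confidence vectors) contribute their ranked feature lists.
Within each list, features are ranked by descending importance; the
consensus order sorts by occurrence count across the ten lists
(descending), then average within-list rank (ascending), then feature
id.  The occurrence-first rule operationalises "most commonly occurring";
the alternative -- pure average rank with an absent-feature penalty of
`list length + 1` -- is available as `method = "avg_rank"`.  Taking
top-$k$ prefixes for every $k$ from 4 to 200 yields 197 nested
signatures; the grid is configurable and the minimum of 4 is kept as the
conventional default.

Signatures are evaluated with seven standard binary classifiers -- kNN,
LDA, random forest, linear-kernel SVM, PLS-DA, naive Bayes and
XGBoost -- under stratified 5-fold cross-validation repeated 10 times.
Each backend is the established library implementation at its default
settings (`class::knn` with $k=5$, `MASS::lda`,
`randomForest::randomForest`, `e1071::svm` with Platt-scaled
probabilities, `mixOmics::plsda` with 2 components, `e1071::naiveBayes`,
and `xgboost` with the logistic objective, 100 rounds, one thread).
Features are standardised with the training fold's statistics.  Each
held-out fold yields one MCC and one (full-grid) AUPR; reported values
are means over the 50 fold-evaluations.  The PLS-DA component count of 2
and the XGBoost round count are the only settings not dictated by a
library default; both are documented here and fixed.

Signature abundance is visualised via log2 fold-change relative to the
feature's cohort mean, $\log_2\!\big((a_{fs}+\varepsilon) /
(\bar a_f+\varepsilon)\big)$, with pseudo-count $\varepsilon$ set to half
the smallest non-zero abundance of the matrix so that all-zero features
map to a flat zero profile rather than NaN.

# Wisdom of the crowd

Aggregated predictions average the members' confidences per sample and
task.  Before aggregating, one seeded-random representative is kept per
(team, feature-selection, classifier) combination and submissions flagged
as inverted -- label-swapped predictions scoring better than random --
are excluded; an advisory detector flags submissions whose inverted
confidences beat the null on at least two tasks, but exclusion is always
an explicit input.  The random-subset experiment scores aggregates over
all combinations of a given size, or over 1,000 sampled *distinct*
combinations when more exist (distinctness is enforced for
reproducibility).  The robustness experiment removes the three best and
three worst members, then re-adds them one by one in each direction;
"best" and "worst" are defined by the same (task, metric) being reported.
The taxonomy-function pairing scores each matched pair and its
two-member aggregate and compares them cohort-wide with paired Wilcoxon
signed-rank tests.

# The synthetic scenario

The generator exists so that every stage above is exercised end-to-end
with known ground truth.  Its defaults are the study conditions the
package is designed around, chosen once:

* **Cohort**: 105 samples, multinomial labels with proportions
  CD/UC/nonIBD = 0.35/0.25/0.40.
* **Profiles**: 300 taxa and 250 pathways, log-normal abundances with
  spread 1.5 on the log scale; 20 informative features receive a
  log-scale group shift of 1.0 (alternating sign).  Taxonomy columns are
  normalised to percentages; pathway columns are left on their raw
  non-negative scale.
* **Diversity structure**: each sample carries a latent position
  $u \sim \mathrm{Beta}(2,2)$.  IBD samples get a dominance exponent
  $1 + 0.8(1-u)$ (lower Shannon diversity on average, higher
  heterogeneity) and an informative-feature shift attenuated by $u$:
  high-diversity IBD samples regress towards nonIBD profiles.  nonIBD
  samples get exponent $1 + 0.4u$ plus an IBD-ward contamination
  $0.6u$ of their informative features: low-diversity nonIBD samples
  drift towards IBD.  Sample difficulty is $0.15 + 0.7u$ for IBD and
  $0.55u$ for nonIBD, which reproduces the qualitative pattern that IBD
  samples are misclassified more often, with misclassification rising
  with diversity in IBD and falling with diversity in nonIBD.
* **Submissions**: confidences are Beta-distributed with mean
  $0.5 + 0.5\,s\,q_{\mathrm{eff}}$ (concentration 6), where $s = \pm 1$
  encodes the gold class and
  $q_{\mathrm{eff}} = q \cdot \mathrm{att}_{task} (1 - 2d_s)$ combines
  submission quality $q$, per-task attenuation and sample difficulty
  $d_s$.  Quality 0 yields exchangeable confidences; quality 1 with zero
  difficulty is special-cased to deterministic 0/1 values so the
  construction limit (MCC = 1) holds exactly.  The default task
  attenuation (1, 0.9, 0.8, 0.25) makes the CD-versus-UC task nearly
  unlearnable, mirroring the near-random performance observed on it.
  Feature-importance lists hold 120 features, informative ones first in
  proportion to quality, so ten top lists always cover the 200-feature
  consensus grid.
* **Submission sets**: 44 distinct profile-based submissions on a quality
  grid from 0.15 to 0.9, plus 16 engineered binarized-duplicate pairs
  from a single heavy-submitting team (60 in total per data type, 44
  surviving deduplication), about 5% inverted submissions, and 17
  raw-based submissions.

What the generator does *not* emulate: read-level sequencing noise,
compositional count sampling (abundances are log-normal ratios rather
than Dirichlet-multinomial counts, a deliberate simplification since the
pipeline consumes relative abundances), taxonomic hierarchy beyond one
annotated level, and any correlation structure among non-informative
features.  Passing tests on this scenario therefore demonstrate the
correctness and calibration of the *evaluation machinery*, not the
difficulty of any real diagnostic problem.

One consequence worth knowing: with all group effects switched off, the
pathway matrix carries no group signal at all, but taxonomy *shares* can
still differ slightly between groups because per-sample normalisation
couples features to the group-specific heterogeneity -- a real property
of compositional data, not a generator artefact.

# Problem sizes and numerical choices in the tests

The shipped test-suite and acceptance script scale the simulations to
desk sizes chosen as their study conditions: 10,000 null draws in the
acceptance script (2,000 for the calibration experiment, with 1,000
fresh trials), 300 draws per seed inside the 50-seed quality-recovery
loop, 5-fold cross-validation with 2 repeats in classifier tests, and
subset caps of 200 combinations in the crowd experiments.  Exhaustive
oracles run on 12-sample instances (all 4,094 informative label
patterns).

# Known limitations

* The restricted AUPR grid makes the metric sensitive to calibration,
  not only ranking; submissions concentrated below 0.5 are penalised by
  construction.  This matches the challenge definition and is therefore
  intentional.
* Percentile interpolation at the null threshold can move borderline
  submissions across the significance boundary by one rank; both rules
  are provided.
* The classifier harness reports mean fold scores only; per-fold
  distributions are not retained.
* Inverted-submission detection is advisory and never excludes
  automatically.

```{r example, eval = FALSE}
# A complete miniature run
cfg <- scenario_config(seed = 1)
sim <- simulate_challenge(cfg)
nulls <- build_null_set(sim$gold, n_draws = 2000, seed = 1)
scores <- add_significance(score_submissions(sim$sc2, sim$gold), nulls)
board <- build_leaderboard(scores)
head(board)
```
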