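# Synthetic challenge generator: three-class cohort, group-structured
# taxonomy/pathway abundance matrices, and submissions of controllable
# quality (including binarized duplicates and inverted submissions), so
# the whole evaluation pipeline runs without external data.

#' Scenario configuration for the synthetic challenge
#'
#' Defaults emulate the study conditions the pipeline was designed for: a
#' 105-sample three-class cohort, 300 taxa / 250 pathways with 20
#' informative features, lower alpha diversity in the IBD group, 60
#' profile-based (SC2) submissions containing 16 engineered
#' binarized-duplicate pairs (44 distinct) and 17 raw-based (SC1)
#' submissions, with roughly 5% inverted submissions.  Task attenuation
#' makes the UC-versus-CD discrimination nearly unlearnable, mirroring the
#' near-random performance observed on that task.
#'
#' @param n_samples Cohort size.
#' @param class_proportions Named proportions over CD/UC/nonIBD; sum to 1.
#' @param n_taxa,n_pathways Feature counts of the two matrices.
#' @param n_informative Number of informative (group-shifted) features.
#' @param effect_size Log-scale abundance shift on informative features.
#' @param diversity_offset Dominance-exponent offset lowering IBD
#'   diversity (0 = no group difference).
#' @param contamination IBD-ward shift applied to difficult nonIBD
#'   samples' informative features.
#' @param quality_range Range of submission qualities in `[0, 1]`.
#' @param n_sc1,n_sc2_unique Numbers of SC1 submissions and of distinct
#'   SC2 submissions.
#' @param n_duplicate_pairs Engineered binarized-duplicate SC2 pairs.
#' @param inverted_fraction Fraction of submissions generated inverted.
#' @param concentration Beta concentration of confidence draws.
#' @param task_attenuation Per-task multiplier on effective quality.
#' @param seed Master seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_samples = 105,
                            class_proportions = c(CD = 0.35, UC = 0.25,
                                                  nonIBD = 0.40),
                            n_taxa = 300, n_pathways = 250,
                            n_informative = 20, effect_size = 1.0,
                            diversity_offset = 0.8, contamination = 0.6,
                            quality_range = c(0.15, 0.9),
                            n_sc1 = 17, n_sc2_unique = 44,
                            n_duplicate_pairs = 16,
                            inverted_fraction = 0.05,
                            concentration = 6,
                            task_attenuation = c(IBDvsNonIBD = 1,
                                                 CDvsNonIBD = 0.9,
                                                 UCvsNonIBD = 0.8,
                                                 CDvsUC = 0.25),
                            seed = 1L) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            n_informative <= min(n_taxa, n_pathways),
            n_duplicate_pairs <= n_sc2_unique,
            all(quality_range >= 0 & quality_range <= 1))
  cfg <- list(n_samples = n_samples, class_proportions = class_proportions,
              n_taxa = n_taxa, n_pathways = n_pathways,
              n_informative = n_informative, effect_size = effect_size,
              diversity_offset = diversity_offset, contamination = contamination,
              quality_range = quality_range, n_sc1 = n_sc1,
              n_sc2_unique = n_sc2_unique, n_duplicate_pairs = n_duplicate_pairs,
              inverted_fraction = inverted_fraction,
              concentration = concentration,
              task_attenuation = task_attenuation, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate the synthetic cohort
#'
#' Labels are drawn from a seeded multinomial over the class proportions.
#' Each sample also receives a latent "position" `u` in `[0, 1]` that the
#' abundance generator converts into within-group diversity and that sets
#' the sample's classification difficulty: high-`u` IBD samples are more
#' diverse and resemble nonIBD profiles (hard), high-`u` nonIBD samples
#' are less diverse and drift towards IBD profiles (hard).
#'
#' @param cfg A `scenario_config`.
#' @return A `gold_standard`; per-sample latents are attached as the
#'   `"latent"` attribute (tibble `sample_id`, `u`, `difficulty`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(child_seed(cfg$seed, "cohort"))
  labels <- sample(names(cfg$class_proportions), cfg$n_samples, replace = TRUE,
                   prob = cfg$class_proportions)
  expected <- cfg$n_samples * cfg$class_proportions
  if (any(expected[unique(labels)] == 0)) {
    stop("class with zero expected samples", call. = FALSE)
  }
  ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  gold <- gold_standard(stats::setNames(labels, ids))
  u <- stats::rbeta(cfg$n_samples, 2, 2)
  ibd <- labels != "nonIBD"
  difficulty <- ifelse(ibd, 0.15 + 0.7 * u, 0.55 * u)
  attr(gold, "latent") <- tibble::tibble(sample_id = ids, u = u,
                                         difficulty = difficulty)
  gold
}

#' Generate a group-structured abundance matrix
#'
#' Log-normal abundances with group mean shifts on the informative
#' features.  IBD samples receive (a) a dominance exponent
#' `1 + diversity_offset * (1 - u)` that concentrates mass on abundant
#' features and lowers Shannon diversity, and (b) an informative-feature
#' shift attenuated by `u`, so that high-diversity IBD samples regress
#' towards nonIBD profiles.  Difficult (high-`u`) nonIBD samples get a
#' milder dominance exponent plus an IBD-ward contamination of their
#' informative features.  Taxonomy matrices are normalised to sum 100 per
#' sample; pathway matrices stay on an arbitrary non-negative scale.
#'
#' @param cfg A `scenario_config`.
#' @param gold Cohort from [generate_cohort()] (carrying latents).
#' @param kind `"taxonomy"` or `"function"`.
#' @return An `abundance_matrix`; the informative feature ids are attached
#'   as the `"informative"` attribute.
#' @export
generate_abundance <- function(cfg, gold, kind = c("taxonomy", "function")) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "scenario_config"))
  latent <- attr(gold, "latent")
  if (is.null(latent)) {
    stop("gold standard lacks the generator's latent attribute; ",
         "use generate_cohort()", call. = FALSE)
  }
  set.seed(child_seed(cfg$seed, "abundance", kind))
  n_feat <- if (kind == "taxonomy") cfg$n_taxa else cfg$n_pathways
  prefix <- if (kind == "taxonomy") "Tax" else "Path"
  feats <- sprintf("%s%04d", prefix, seq_len(n_feat))
  informative <- feats[seq_len(cfg$n_informative)]
  base_mu <- stats::rnorm(n_feat, 0, 1.5)
  shift_dir <- rep(c(1, -1), length.out = cfg$n_informative)
  shift <- numeric(n_feat)
  shift[seq_len(cfg$n_informative)] <- shift_dir * cfg$effect_size
  labels <- gold_label_vector(gold)
  u <- stats::setNames(latent$u, latent$sample_id)
  m <- matrix(0, nrow = n_feat, ncol = nrow(gold),
              dimnames = list(feats, gold$sample_id))
  for (s in gold$sample_id) {
    ibd <- labels[[s]] != "nonIBD"
    mult <- if (ibd) 1 - u[[s]] else cfg$contamination * u[[s]]
    noise_sd <- if (ibd) 0.8 else 0.6  # higher within-IBD heterogeneity
    log_a <- base_mu + shift * mult + stats::rnorm(n_feat, 0, noise_sd)
    theta <- if (ibd) 1 + cfg$diversity_offset * (1 - u[[s]])
             else 1 + 0.5 * cfg$diversity_offset * u[[s]]
    m[, s] <- exp(log_a * theta)
  }
  if (kind == "taxonomy") {
    m <- sweep(m, 2, colSums(m), "/") * 100
    out <- abundance_matrix(m, kind = "taxonomy", level = "Species")
  } else {
    out <- abundance_matrix(m, kind = "function")
  }
  attr(out, "informative") <- informative
  out
}

#' Generate a participant submission of controllable quality
#'
#' Per task, a sample's confidence is drawn from a Beta distribution whose
#' mean is `0.5 + 0.5 * s * q_eff`, where `s` is +1 for class-1 samples,
#' -1 for class-2 samples and 0 out of scope, and the effective quality
#' `q_eff = quality * attenuation * (1 - 2 * difficulty)` shrinks -- and
#' eventually flips -- for difficult samples.  Quality 0 gives identical
#' class-conditional distributions; quality 1 with zero difficulty gives
#' deterministic 0/1 confidences (hence MCC 1).  `inverted = TRUE` returns
#' `1 - confidence`.
#'
#' @param quality Separation quality in `[0, 1]`.
#' @param gold A `gold_standard`.
#' @param seed Integer seed.
#' @param inverted Return label-swapped confidences.
#' @param difficulty Optional named per-sample difficulty in `[0, 1]`
#'   (default 0 for all samples).
#' @param task_attenuation Named per-task multipliers (default 1).
#' @param concentration Beta concentration (larger = less noise).
#' @param tasks Task list.
#' @param informative Optional pool of informative feature ids used to
#'   build a quality-consistent feature-importance list.
#' @param feature_pool Optional full feature id pool for the list's tail.
#' @param n_features_list Length of the importance list (default 120,
#'   mirroring signatures in the tens-to-hundreds range).
#' @inheritParams submission
#' @return A `submission`.
#' @export
generate_submission <- function(quality, gold, seed = 1L, inverted = FALSE,
                                difficulty = NULL, task_attenuation = NULL,
                                concentration = 6, tasks = challenge_tasks(),
                                submission_id = sprintf("sub_q%.2f", quality),
                                team_id = submission_id,
                                sub_challenge = "SC2", data_type = "taxonomy",
                                method_tags = c(feature_selection = "synthetic",
                                                classifier = "synthetic"),
                                informative = NULL, feature_pool = NULL,
                                n_features_list = 120) {
  stopifnot(quality >= 0, quality <= 1)
  set.seed(as.integer(seed))
  if (is.null(difficulty)) {
    difficulty <- stats::setNames(rep(0, nrow(gold)), gold$sample_id)
  }
  if (is.null(task_attenuation)) {
    task_attenuation <- stats::setNames(rep(1, length(tasks)), names(tasks))
  }
  conf <- lapply(tasks, function(task) {
    cls <- gold_classes(gold, task)
    s_dir <- ifelse(is.na(cls), 0, ifelse(cls == 1L, 1, -1))
    att <- task_attenuation[[task$name]]
    q_eff <- quality * att * (1 - 2 * difficulty[gold$sample_id])
    mu <- 0.5 + 0.5 * s_dir * q_eff
    exact <- quality == 1 & att == 1 & difficulty[gold$sample_id] == 0 & s_dir != 0
    mu_c <- pmin(0.98, pmax(0.02, mu))
    p <- stats::rbeta(length(mu_c), concentration * mu_c,
                      concentration * (1 - mu_c))
    p[exact] <- (s_dir[exact] + 1) / 2
    stats::setNames(p, gold$sample_id)
  })
  names(conf) <- names(tasks)
  if (inverted) conf <- lapply(conf, function(p) 1 - p)
  fi <- NULL
  if (!is.null(informative)) {
    if (is.null(feature_pool)) feature_pool <- informative
    pool <- unique(c(informative, feature_pool))
    score <- quality * as.numeric(pool %in% informative) +
      stats::runif(length(pool)) * 0.5
    ord <- order(-score)
    keep <- ord[seq_len(min(n_features_list, length(pool)))]
    fi <- tibble::tibble(feature_id = pool[keep],
                         importance = sort(score[keep], decreasing = TRUE))
  }
  submission(submission_id, conf, team_id = team_id,
             sub_challenge = sub_challenge, data_type = data_type,
             method_tags = method_tags, feature_importances = fi)
}

# Copy a submission, redrawing every confidence uniformly within the same
# side of the threshold so the binarized pattern is preserved exactly.
make_binarized_duplicate <- function(sub, seed, new_id) {
  set.seed(as.integer(seed))
  out <- sub
  out$submission_id <- new_id
  out$confidences <- lapply(sub$confidences, function(p) {
    hi <- p > 0.5
    q <- numeric(length(p))
    q[hi] <- stats::runif(sum(hi), 0.5 + 1e-9, 1)
    q[!hi] <- stats::runif(sum(!hi), 0, 0.5)
    stats::setNames(q, names(p))
  })
  out
}

#' Simulate a full synthetic challenge
#'
#' Generates the cohort, both abundance matrices and the SC1/SC2
#' submission sets of the scenario: distinct SC2 submissions on a quality
#' grid (each with taxonomy and function variants and a feature-importance
#' list), engineered binarized-duplicate pairs from one heavy-submitting
#' team, inverted submissions, and SC1 raw-based submissions.
#'
#' @param cfg A `scenario_config`.
#' @return List with elements `gold`, `taxonomy`, `functional`, `sc1`
#'   (list of submissions), `sc2` (list of submissions, taxonomy and
#'   function entries interleaved) and `manifest` (true parameters:
#'   qualities, inverted ids, duplicate pairs, informative features,
#'   per-sample difficulty).
#' @export
simulate_challenge <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  gold <- generate_cohort(cfg)
  taxonomy <- generate_abundance(cfg, gold, "taxonomy")
  functional <- generate_abundance(cfg, gold, "function")
  latent <- attr(gold, "latent")
  difficulty <- stats::setNames(latent$difficulty, latent$sample_id)
  set.seed(child_seed(cfg$seed, "submissions"))
  fs_pool <- c("lasso", "mRMR", "varImp", "none")
  cl_pool <- c("RF", "XGBoost", "SVM", "kNN", "LDA", "NB", "PLS-DA")

  n2 <- cfg$n_sc2_unique
  qual2 <- sample(seq(cfg$quality_range[1], cfg$quality_range[2],
                      length.out = n2))
  n_inv <- round(cfg$inverted_fraction * n2)
  inverted2 <- sort(sample.int(n2, n_inv))
  dup_sources <- sort(sample.int(n2, cfg$n_duplicate_pairs))
  team2 <- sprintf("T%02d", sample.int(max(8, ceiling(n2 / 3)), n2, replace = TRUE))
  team2[dup_sources] <- "T01"  # duplicate pairs all come from one team
  tags2 <- lapply(seq_len(n2), function(i) {
    c(feature_selection = sample(fs_pool, 1), classifier = sample(cl_pool, 1))
  })
  sc2 <- list()
  manifest_rows <- list()
  for (i in seq_len(n2)) {
    id <- sprintf("SC2_%02d", i)
    inv <- i %in% inverted2
    for (dt in c("taxonomy", "function")) {
      mat <- if (dt == "taxonomy") taxonomy else functional
      sub <- generate_submission(
        qual2[i], gold, seed = child_seed(cfg$seed, "sc2", i, dt),
        inverted = inv, difficulty = difficulty,
        task_attenuation = cfg$task_attenuation,
        concentration = cfg$concentration, submission_id = id,
        team_id = team2[i], sub_challenge = "SC2", data_type = dt,
        method_tags = tags2[[i]],
        informative = attr(mat, "informative"),
        feature_pool = rownames(mat$abundance))
      sc2[[length(sc2) + 1]] <- sub
    }
    manifest_rows[[i]] <- tibble::tibble(submission_id = id, team_id = team2[i],
                                         quality = qual2[i], inverted = inv,
                                         duplicate_of = NA_character_)
  }
  dup_pairs <- character(0)
  for (j in seq_along(dup_sources)) {
    i <- dup_sources[j]
    src_id <- sprintf("SC2_%02d", i)
    new_id <- sprintf("SC2_%02dd", i)
    src_subs <- Filter(function(s) s$submission_id == src_id, sc2)
    for (src in src_subs) {
      dup <- make_binarized_duplicate(
        src, seed = child_seed(cfg$seed, "dup", i, src$data_type), new_id = new_id)
      sc2[[length(sc2) + 1]] <- dup
    }
    dup_pairs <- c(dup_pairs, paste(src_id, new_id, sep = ":"))
    manifest_rows[[length(manifest_rows) + 1]] <-
      tibble::tibble(submission_id = new_id, team_id = "T01",
                     quality = qual2[i], inverted = i %in% inverted2,
                     duplicate_of = src_id)
  }

  n1 <- cfg$n_sc1
  qual1 <- sample(seq(cfg$quality_range[1], cfg$quality_range[2],
                      length.out = n1))
  sc1 <- lapply(seq_len(n1), function(i) {
    generate_submission(
      qual1[i], gold, seed = child_seed(cfg$seed, "sc1", i),
      difficulty = difficulty, task_attenuation = cfg$task_attenuation,
      concentration = cfg$concentration,
      submission_id = sprintf("SC1_%02d", i),
      team_id = sprintf("R%02d", i), sub_challenge = "SC1", data_type = "raw",
      method_tags = c(feature_selection = sample(fs_pool, 1),
                      classifier = sample(cl_pool, 1)))
  })

  list(gold = gold, taxonomy = taxonomy, functional = functional,
       sc1 = sc1, sc2 = sc2,
       manifest = list(
         submissions = dplyr::bind_rows(manifest_rows),
         sc1_qualities = qual1,
         duplicate_pairs = dup_pairs,
         inverted_ids = sprintf("SC2_%02d", inverted2),
         informative_taxa = attr(taxonomy, "informative"),
         informative_pathways = attr(functional, "informative"),
         difficulty = difficulty))
}

#' Write a simulated challenge to disk
#'
#' Emits the gold standard CSV, the two abundance TSVs (taxonomy with its
#' description companion), one CSV plus feature list per submission, and
#' a YAML manifest of the true generating parameters.
#'
#' @param sim Output of [simulate_challenge()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gold_standard(sim$gold, file.path(dir, "gold_standard.csv"))
  write_abundance_matrix(sim$taxonomy, file.path(dir, "taxonomy.tsv"),
                         file.path(dir, "taxonomy_description.csv"))
  write_abundance_matrix(sim$functional, file.path(dir, "function.tsv"))
  subdir <- file.path(dir, "submissions")
  dir.create(subdir, showWarnings = FALSE)
  for (sub in c(sim$sc1, sim$sc2)) {
    stem <- paste0(sub$submission_id, "_", sub$data_type)
    write_submission(sub, file.path(subdir, paste0(stem, ".csv")))
    if (!is.null(sub$feature_importances)) {
      write_feature_list(sub$feature_importances,
                         file.path(subdir, paste0(stem, "_features.csv")))
    }
  }
  man <- sim$manifest
  man$submissions <- as.list(as.data.frame(man$submissions))
  man$difficulty <- as.list(man$difficulty)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
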