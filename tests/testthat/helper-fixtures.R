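# Shared fixtures and independent oracles, built in code.

# Small balanced gold standard.
tiny_gold <- function(n_cd = 4, n_uc = 3, n_non = 5) {
  labels <- c(rep("CD", n_cd), rep("UC", n_uc), rep("nonIBD", n_non))
  gold_standard(setNames(labels, sprintf("s%02d", seq_along(labels))))
}

# Submission whose confidences encode the gold labels with given accuracy
# margin (1 = perfect hard calls, 0 = all at 0.5).
gold_echo_submission <- function(gold, margin = 1, id = "echo",
                                 flip_samples = character()) {
  tasks <- challenge_tasks()
  conf <- lapply(tasks, function(task) {
    cls <- gold_classes(gold, task)
    p <- ifelse(is.na(cls), 0.5, ifelse(cls == 1L, 0.5 + margin / 2,
                                        0.5 - margin / 2))
    p[names(cls) %in% flip_samples] <- 1 - p[names(cls) %in% flip_samples]
    setNames(p, names(cls))
  })
  names(conf) <- names(tasks)
  submission(id, conf, sub_challenge = "SC2", data_type = "taxonomy")
}

# Independent average-precision oracle: explicit counting at every
# distinct confidence value (descending), step-integrated by recall
# increments.  No shared code with the package's implementation.
oracle_average_precision <- function(p, y) {
  stopifnot(length(p) == length(y), any(y))
  thresholds <- sort(unique(p), decreasing = TRUE)
  n_pos <- sum(y)
  prev_rec <- 0
  ap <- 0
  for (t in thresholds) {
    tp <- 0; fp <- 0
    for (i in seq_along(p)) {
      if (p[i] >= t) {
        if (y[i]) tp <- tp + 1 else fp <- fp + 1
      }
    }
    rec <- tp / n_pos
    prec <- if (tp + fp > 0) tp / (tp + fp) else 1
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# MCC oracle: Pearson correlation of the two binary indicators.
oracle_mcc <- function(pred1, gold1) {
  r <- suppressWarnings(cor(as.numeric(pred1), as.numeric(gold1)))
  if (is.na(r)) 0 else r
}

# Two-class gold over n samples from a logical class-1 indicator.
indicator_gold <- function(is_cd, ids = sprintf("x%02d", seq_along(is_cd))) {
  gold_standard(setNames(ifelse(is_cd, "CD", "nonIBD"), ids))
}
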