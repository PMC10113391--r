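# Classifier backends and the repeated stratified cross-validation
# harness used to evaluate individual and consensus signatures.

#' Names of the supported classifiers
#' @return Character vector of the seven classifier names.
#' @export
cv_classifiers <- function() {
  c("kNN", "LDA", "RF", "SVMlinear", "PLS-DA", "NB", "XGBoost")
}

# Fit one classifier on (Xtr, ytr) and return P(class 1) on Xte.
# y is a factor whose FIRST level is class 1.  Backends run at library
# defaults (kNN k = 5, PLS-DA with 2 components, XGBoost logistic with
# 100 rounds, single thread for reproducibility).
fit_predict <- function(method, Xtr, ytr, Xte) {
  pos <- levels(ytr)[1]
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("classifier backend requires package ", pkg, call. = FALSE)
    }
  }
  switch(method,
    "kNN" = {
      need("class")
      pred <- class::knn(Xtr, Xte, cl = ytr, k = 5, prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == pos, pr, 1 - pr)
    },
    "LDA" = {
      need("MASS")
      keep <- apply(Xtr, 2, stats::sd) > 0
      fit <- MASS::lda(Xtr[, keep, drop = FALSE], grouping = ytr)
      unname(stats::predict(fit, Xte[, keep, drop = FALSE])$posterior[, pos])
    },
    "RF" = {
      need("randomForest")
      fit <- randomForest::randomForest(Xtr, y = ytr)
      unname(stats::predict(fit, Xte, type = "prob")[, pos])
    },
    "SVMlinear" = {
      need("e1071")
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", probability = TRUE)
      pr <- attr(stats::predict(fit, Xte, probability = TRUE), "probabilities")
      unname(pr[, pos])
    },
    "PLS-DA" = {
      need("mixOmics")
      fit <- mixOmics::plsda(Xtr, ytr, ncomp = 2)
      pr <- stats::predict(fit, Xte)$predict[, pos, 2]
      pmin(1, pmax(0, unname(pr)))
    },
    "NB" = {
      need("e1071")
      fit <- e1071::naiveBayes(Xtr, ytr)
      unname(stats::predict(fit, Xte, type = "raw")[, pos])
    },
    "XGBoost" = {
      need("xgboost")
      dtr <- xgboost::xgb.DMatrix(Xtr, label = as.numeric(ytr == pos),
                                  nthread = 1)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              nthread = 1),
                                data = dtr, nrounds = 100)
      unname(stats::predict(fit, Xte))
    },
    stop("unknown classifier: ", method, call. = FALSE)
  )
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds, so every fold keeps both classes.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified cross-validation of a feature signature
#'
#' Evaluates a feature signature on an abundance matrix with a panel of
#' binary classifiers under `folds`-fold stratified cross-validation
#' repeated `repeats` times.  Each held-out fold yields one MCC
#' (probabilities binarised at 0.5) and one AUPR (full-range
#' precision-recall grid); the reported scores are means over all
#' `folds * repeats` fold-evaluations.  Features are standardised with the
#' training fold's mean and standard deviation before fitting.
#'
#' @param signature Character vector of feature ids to use.
#' @param x An `abundance_matrix` (or plain features-by-samples matrix).
#' @param labels Factor over the matrix's samples; the first level is
#'   class 1, the positive class.  Samples with `NA` labels are dropped.
#' @param classifiers Subset of [cv_classifiers()].
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed; the whole evaluation is reproducible.
#' @return Tibble: `classifier`, `mcc`, `aupr`, `folds`, `repeats`, `seed`.
#' @export
cv_evaluate <- function(signature, x, labels, classifiers = cv_classifiers(),
                        folds = 5, repeats = 10, seed = 1L) {
  m <- if (inherits(x, "abundance_matrix")) x$abundance else as.matrix(x)
  missing <- setdiff(signature, rownames(m))
  if (length(missing) > 0) {
    stop("feature(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  classifiers <- match.arg(classifiers, cv_classifiers(), several.ok = TRUE)
  labels <- factor(labels)
  keep <- !is.na(labels)
  X <- t(m[signature, keep, drop = FALSE])
  y <- droplevels(labels[keep])
  if (nlevels(y) != 2) stop("labels must have exactly two classes", call. = FALSE)
  if (min(table(y)) < folds) {
    stop("each class needs at least as many samples as folds", call. = FALSE)
  }
  if (all(apply(X, 2, stats::sd) == 0)) {
    stop("degenerate signature: all features constant", call. = FALSE)
  }
  pos <- levels(y)[1]
  scores <- array(NA_real_, dim = c(length(classifiers), repeats * folds, 2),
                  dimnames = list(classifiers, NULL, c("mcc", "aupr")))
  for (rep_i in seq_len(repeats)) {
    set.seed(child_seed(seed, "cv", rep_i))
    fold_of <- stratified_folds(y, folds)
    for (fold_i in seq_len(folds)) {
      te <- fold_of == fold_i
      mu <- colMeans(X[!te, , drop = FALSE])
      sdv <- apply(X[!te, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(X[!te, , drop = FALSE], 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
      y_te <- y[te] == pos
      col <- (rep_i - 1) * folds + fold_i
      for (cl in classifiers) {
        set.seed(child_seed(seed, "fit", cl, rep_i, fold_i))
        p <- fit_predict(cl, Xtr, y[!te], Xte)
        pred1 <- p > 0.5
        tp <- sum(pred1 & y_te); fp <- sum(pred1 & !y_te)
        fn <- sum(!pred1 & y_te); tn <- sum(!pred1 & !y_te)
        scores[cl, col, "mcc"] <- mcc(structure(
          list(tp = tp, fp = fp, tn = tn, fn = fn), class = "confusion_counts"))
        thr <- sort(unique(c(1, 0, p[p > 0 & p <= 1])), decreasing = TRUE)
        scores[cl, col, "aupr"] <- aupr_from_points(p, y_te, thr)
      }
    }
  }
  means <- apply(scores, c(1, 3), mean)
  tibble::tibble(classifier = classifiers,
                 mcc = unname(means[, "mcc"]),
                 aupr = unname(means[, "aupr"]),
                 folds = folds, repeats = repeats, seed = as.integer(seed))
}
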