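#' Stratified cross-validation fold assignment
#'
#' Assigns samples to `k` folds such that (a) overall fold sizes differ by
#' at most one and (b) each class's per-fold count differs by at most one
#' from an even split, so the class ratio of every fold is within one
#' patient of the global ratio. Classes are shuffled independently and the
#' folds receiving each class's remainder are rotated cyclically, which is
#' what keeps the total fold sizes balanced. Deterministic given `seed`.
#'
#' @param labels Binary 0/1 vector (both classes present).
#' @param k Number of folds (at most the minority-class count).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, same length/order as
#'   `labels`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    abort_validation("stratification requires both classes to be present")
  k <- as.integer(k)
  if (k < 2L) abort_validation("k must be >= 2")
  if (k > min(table(labels)))
    abort_validation("k exceeds the minority class count")
  set.seed(seed)
  folds <- integer(length(labels))
  offset <- 0L
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    base <- n_c %/% k
    r <- n_c %% k
    sizes <- rep(base, k)
    if (r > 0L) {
      extra <- ((offset + seq_len(r) - 1L) %% k) + 1L
      sizes[extra] <- sizes[extra] + 1L
      offset <- offset + r
    }
    folds[idx] <- rep(seq_len(k), times = sizes)
  }
  folds
}

#' Classification metrics from a confusion matrix
#'
#' All rates are percentages. Degenerate cells follow fixed conventions:
#' precision is 0 when nothing is predicted positive, F1 is 0 when
#' precision and recall are both degenerate.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (total > 0).
#' @return Named numeric vector: `recall`, `precision`, `specificity`,
#'   `balanced_accuracy`, `f1` (percent).
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || sum(counts) == 0)
    abort_validation("confusion counts must be non-negative with a positive total")
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  specificity <- if (tn + fp == 0) 0 else tn / (tn + fp)
  ba <- (recall + specificity) / 2
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  100 * c(recall = recall, precision = precision, specificity = specificity,
          balanced_accuracy = ba, f1 = f1)
}

#' Rank-based ROC curve and AUC
#'
#' AUC is the probability that a randomly chosen positive outranks a
#' randomly chosen negative, with ties counted one half — the
#' Mann-Whitney formulation, computed from mid-ranks. The ROC curve is
#' traced over all score thresholds.
#'
#' @param scores Real-valued classifier scores (higher = more positive).
#' @param labels Binary 0/1 vector, both classes present.
#' @return List with `auc` and `curve` (data frame: threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    abort_validation("AUC is undefined with a single class")
  if (length(scores) != length(labels) || anyNA(scores))
    abort_validation("scores must be real-valued, one per label")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(l, grp, sum)
  fpn <- tapply(1 - l, grp, sum)
  curve <- data.frame(
    threshold = s[!duplicated(s)],
    fpr = cumsum(fpn) / n_neg,
    tpr = cumsum(tp) / n_pos,
    row.names = NULL
  )
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), curve)
  list(auc = unname(auc), curve = curve)
}

# training-fold standardization, applied to a test fold without touching it
fit_standardizer <- function(train) {
  ctr <- colMeans(train)
  scl <- apply(train, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2L, std$center, "-"), 2L, std$scale, "/")
}

# --- per-classifier train/score backends -----------------------------------
# Each returns list(pred = 0/1 vector, score = positive-class score) on the
# test split. Features arrive already standardized on training statistics.

fit_score_svm <- function(xtr, ytr, xte, cost = 1) {
  fac <- factor(ytr, levels = c(0, 1))
  fit <- e1071::svm(xtr, fac, kernel = "linear", cost = cost, scale = FALSE)
  pr <- stats::predict(fit, xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071 orients the margin toward the first class named in the column label
  score <- if (startsWith(colnames(dv)[1L], "1")) dv[, 1L] else -dv[, 1L]
  list(pred = as.integer(as.character(pr)), score = as.numeric(score))
}

fit_score_rf <- function(xtr, ytr, xte, ntree = 200) {
  fac <- factor(ytr, levels = c(0, 1))
  fit <- randomForest::randomForest(xtr, fac, ntree = ntree)
  prob <- stats::predict(fit, xte, type = "prob")[, "1"]
  list(pred = as.integer(prob > 0.5), score = as.numeric(prob))
}

fit_score_knn <- function(xtr, ytr, xte, k = 5) {
  pr <- class::knn(xtr, xte, factor(ytr, levels = c(0, 1)), k = k, prob = TRUE)
  win <- attr(pr, "prob")                # vote fraction of the winning class
  pred <- as.integer(as.character(pr))
  score <- ifelse(pred == 1L, win, 1 - win)
  list(pred = pred, score = as.numeric(score))
}

#' Stratified cross-validated classifier evaluation
#'
#' Runs the full evaluation protocol on a refined (or raw) feature panel:
#' stratified k-fold assignment, per-fold feature standardization fit on
#' the training split only (no leakage into the held-out fold), training of
#' a linear-kernel SVM (C = 1), a 200-tree random forest, and a
#' 5-nearest-neighbour classifier, and per-fold balanced accuracy,
#' precision, recall and F1 (percent) plus a pooled out-of-fold ROC/AUC per
#' classifier. Fully reproducible given `seed`.
#'
#' @param x A `refined_set` or [feature_matrix()].
#' @param labels Binary 0/1 labels, one per patient (defaults to the
#'   labels stored in the matrix).
#' @param config A [serfe_config()] (supplies `cv_folds` and `seed`).
#' @param classifiers Subset of `c("svm", "random_forest", "knn")`.
#' @param cost,ntree,knn_k Classifier hyperparameters (defaults C = 1,
#'   200 trees, k = 5).
#' @return An `eval_report`: per classifier, `folds` (per-fold metrics),
#'   `mean`, `sd`, `auc`, `roc` points, plus `fold_assignment` and `seed`.
#' @export
evaluate_classifiers <- function(x, labels = NULL, config = serfe_config(),
                                 classifiers = c("svm", "random_forest", "knn"),
                                 cost = 1, ntree = 200, knn_k = 5) {
  m <- if (inherits(x, "refined_set")) x$matrix else x
  stopifnot(inherits(m, "feature_matrix"))
  labels <- labels %||% m$labels
  if (is.null(labels)) abort_validation("labels are required for evaluation")
  if (!is.null(names(labels))) labels <- labels[patient_ids(m)]
  labels <- as.integer(labels)
  if (anyNA(labels) || length(labels) != nrow(m$values))
    abort_validation("labels must provide one 0/1 value per patient")
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  k <- config$cv_folds
  folds <- stratified_folds(labels, k = k, seed = config$seed)
  backends <- list(svm = function(a, b, c) fit_score_svm(a, b, c, cost),
                   random_forest = function(a, b, c) fit_score_rf(a, b, c, ntree),
                   knn = function(a, b, c) fit_score_knn(a, b, c, knn_k))
  report <- list()
  for (cl in classifiers) {
    set.seed(config$seed + match(cl, names(backends)))
    fold_rows <- vector("list", k)
    oof_score <- numeric(length(labels))
    for (f in seq_len(k)) {
      te <- folds == f
      std <- fit_standardizer(m$values[!te, , drop = FALSE])
      xtr <- apply_standardizer(std, m$values[!te, , drop = FALSE])
      xte <- apply_standardizer(std, m$values[te, , drop = FALSE])
      out <- backends[[cl]](xtr, labels[!te], xte)
      yte <- labels[te]
      mt <- classification_metrics(
        tp = sum(out$pred == 1L & yte == 1L),
        fp = sum(out$pred == 1L & yte == 0L),
        tn = sum(out$pred == 0L & yte == 0L),
        fn = sum(out$pred == 0L & yte == 1L))
      fold_rows[[f]] <- data.frame(fold = f, t(mt))
      oof_score[te] <- out$score
    }
    fold_df <- do.call(rbind, fold_rows)
    roc <- roc_auc(oof_score, labels)
    metric_cols <- setdiff(names(fold_df), "fold")
    report[[cl]] <- list(
      folds = fold_df,
      mean = colMeans(fold_df[metric_cols]),
      sd = apply(fold_df[metric_cols], 2L, stats::sd),
      auc = roc$auc,
      roc = roc$curve,
      scores = oof_score
    )
  }
  structure(list(classifiers = report, fold_assignment = folds,
                 seed = config$seed, n = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d patients, %d-fold CV (seed %d)\n",
              x$n, max(x$fold_assignment), x$seed))
  for (cl in names(x$classifiers)) {
    r <- x$classifiers[[cl]]
    cat(sprintf("  %-14s BA %.1f%%  precision %.1f%%  recall %.1f%%  F1 %.1f%%  AUC %.3f\n",
                cl, r$mean[["balanced_accuracy"]], r$mean[["precision"]],
                r$mean[["recall"]], r$mean[["f1"]], r$auc))
  }
  invisible(x)
}
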