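#' Greedy Pearson redundancy filter
#'
#' Scans features in descending priority (ties broken lexicographically by
#' name) and drops a feature if its absolute Pearson correlation with any
#' already-retained feature exceeds `threshold`; the higher-priority member
#' of a correlated pair therefore survives. Zero-variance features, whose
#' correlation is undefined, are treated as redundant and logged with
#' reason `"zero_variance"`. The redundancy rate is the percentage of
#' dropped features relative to the candidate count.
#'
#' @param matrix A [feature_matrix()] with at least 3 patients.
#' @param threshold Absolute correlation cutoff in (0, 1]. Default 0.85.
#' @param priority Optional numeric vector (named by feature or in column
#'   order) ranking features; higher is kept first. Default: all equal, so
#'   the scan order is lexicographic. The pipeline passes the adaptive
#'   weights here.
#' @return List with `matrix` (retained features), `dropped` (data frame:
#'   feature, reason, statistic = the offending |r|), `redundancy_rate`
#'   (percent), and `retained` (names).
#' @export
redundancy_filter <- function(matrix, threshold = 0.85, priority = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  v <- matrix$values
  if (nrow(v) < 3L)
    abort_validation("redundancy filtering needs at least 3 patients")
  feats <- colnames(v)
  p <- length(feats)
  if (is.null(priority)) priority <- rep(0, p)
  if (!is.null(names(priority))) {
    if (!all(feats %in% names(priority)))
      abort_validation("`priority` must cover all features")
    priority <- priority[feats]
  } else if (length(priority) != p) {
    abort_validation("`priority` must cover all features")
  }
  ord <- order(-priority, feats)
  sds <- apply(v, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(v))
  retained <- character(0)
  dropped_f <- character(0); dropped_r <- character(0); dropped_s <- numeric(0)
  for (j in ord) {
    f <- feats[j]
    if (sds[j] == 0) {
      dropped_f <- c(dropped_f, f)
      dropped_r <- c(dropped_r, "zero_variance")
      dropped_s <- c(dropped_s, NA_real_)
      next
    }
    r <- abs(cm[f, retained])
    r <- r[!is.na(r)]
    if (length(r) && max(r) > threshold) {
      dropped_f <- c(dropped_f, f)
      dropped_r <- c(dropped_r, "redundant")
      dropped_s <- c(dropped_s, max(r))
    } else {
      retained <- c(retained, f)
    }
  }
  retained <- feats[feats %in% retained]   # restore input column order
  list(
    matrix = fm_select(matrix, retained),
    dropped = data.frame(feature = dropped_f, reason = dropped_r,
                         statistic = dropped_s, stringsAsFactors = FALSE),
    redundancy_rate = 100 * length(dropped_f) / p,
    retained = retained
  )
}

#' ICC stability estimates from repeated extractions
#'
#' For each feature, decomposes the patients-by-replicates table with the
#' one-way random-effects ANOVA (single measurement, balanced design):
#' `MS_within` estimates the within-subject variance across repeated scans,
#' `(MS_between - MS_within) / k` estimates the between-subject variance
#' (clipped at zero), and the intraclass correlation is
#' `ICC = sigma_b^2 / (sigma_b^2 + sigma_w^2)`, with 0/0 mapped to 0. The
#' estimator is invariant to adding a constant and to common scaling.
#'
#' @param replicates A [replicate_set()] (balanced: same replicate count
#'   for every patient, at least 2 each, at least 2 patients).
#' @return Data frame with `feature`, `icc`, `sigma_b2`, `sigma_w2`,
#'   `ms_between`, `ms_within`.
#' @export
icc_estimate <- function(replicates) {
  stopifnot(inherits(replicates, "replicate_set"))
  arr <- replicates$replicate_values
  n <- dim(arr)[1L]; p <- dim(arr)[2L]; k <- dim(arr)[3L]
  if (n < 2L) abort_validation("ICC estimation needs at least 2 subjects")
  if (k < 2L) abort_validation("ICC estimation needs at least 2 replicates")
  if (anyNA(arr))
    abort_validation("replicate array contains missing values; balanced complete designs only")
  res <- vapply(seq_len(p), function(j) {
    y <- arr[, j, ]                       # n x k
    mi <- rowMeans(y)
    ms_b <- k * sum((mi - mean(mi))^2) / (n - 1)
    ms_w <- sum((y - mi)^2) / (n * (k - 1))
    s_w <- ms_w
    s_b <- max((ms_b - ms_w) / k, 0)
    icc <- if (s_b + s_w == 0) 0 else s_b / (s_b + s_w)
    c(icc, s_b, s_w, ms_b, ms_w)
  }, numeric(5))
  data.frame(
    feature = feature_names(replicates$base),
    icc = res[1L, ], sigma_b2 = res[2L, ], sigma_w2 = res[3L, ],
    ms_between = res[4L, ], ms_within = res[5L, ],
    stringsAsFactors = FALSE
  )
}

#' Stability filter and feature stability score
#'
#' Retains features whose ICC meets the threshold (inclusive) and reports
#' the feature stability score: the percentage of candidate features with
#' ICC at or above the threshold, computed on the candidate set before any
#' dropping.
#'
#' @param iccs Data frame from [icc_estimate()] (or any frame with
#'   `feature` and `icc` columns).
#' @param threshold Minimum ICC, in (0, 1]; comparison is `>=`.
#'   Default 0.75.
#' @return List with `retained` (feature names), `dropped` (data frame:
#'   feature, reason = "unstable", statistic = ICC), and `stability_score`
#'   (percent).
#' @export
stability_filter <- function(iccs, threshold = 0.75) {
  stopifnot(is.data.frame(iccs), all(c("feature", "icc") %in% names(iccs)))
  stable <- iccs$icc >= threshold
  list(
    retained = iccs$feature[stable],
    dropped = data.frame(feature = iccs$feature[!stable],
                         reason = rep("unstable", sum(!stable)),
                         statistic = iccs$icc[!stable],
                         stringsAsFactors = FALSE),
    stability_score = 100 * mean(stable)
  )
}

#' Assemble the quality-filter report
#'
#' Merges the per-stage drop records into one consistent report. Counts are
#' checked for conservation: every initial feature must appear exactly once
#' among retained and dropped.
#'
#' @param initial_features Character vector of features entering the filter
#'   chain.
#' @param retained Character vector of features surviving all stages.
#' @param dropped Data frame (feature, reason, statistic) accumulated over
#'   stages; reasons are `low_entropy`, `redundant`, `zero_variance`,
#'   `unstable`.
#' @param redundancy_rate Percent of candidates dropped as redundant at the
#'   redundancy stage.
#' @param stability_score Percent of candidates with ICC at or above the
#'   threshold, or `NULL` when no replicates were provided (reported as
#'   `"not_assessed"` rather than fabricated).
#' @param iccs Optional per-feature ICC table to embed.
#' @param thresholds Named list of the thresholds used.
#' @return A `filter_report` list.
#' @export
assemble_filter_report <- function(initial_features, retained, dropped,
                                   redundancy_rate, stability_score = NULL,
                                   iccs = NULL, thresholds = list()) {
  if (anyDuplicated(c(retained, dropped$feature)) ||
      !setequal(c(retained, dropped$feature), initial_features))
    serfe_abort("filter report is inconsistent: retained + dropped != initial features",
                "serfe_internal_error")
  structure(
    list(
      n_initial = length(initial_features),
      n_retained = length(retained),
      retained_features = retained,
      dropped = dropped,
      redundancy_rate = redundancy_rate,
      stability_score = stability_score %||% "not_assessed",
      icc = iccs,
      thresholds = thresholds
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d -> %d features; redundancy rate %.1f%%; stability score %s\n",
              x$n_initial, x$n_retained, x$redundancy_rate,
              if (is.character(x$stability_score)) x$stability_score
              else sprintf("%.1f%%", x$stability_score)))
  invisible(x)
}

#' Relative reduction between two redundancy rates
#'
#' Percentage reduction of a refined pipeline's redundancy rate relative to
#' a baseline extractor's rate: `100 * (baseline - refined) / baseline`.
#' Useful for benchmarking against published toolkit redundancy rates.
#'
#' @param baseline_rate Baseline redundancy rate (percent).
#' @param refined_rate Refined redundancy rate (percent).
#' @return Relative reduction in percent.
#' @export
relative_redundancy_reduction <- function(baseline_rate, refined_rate) {
  if (baseline_rate <= 0) abort_validation("baseline rate must be positive")
  100 * (baseline_rate - refined_rate) / baseline_rate
}
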