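#' Run the full feature-refinement pipeline
#'
#' Orchestrates the refinement stages in their canonical order:
#' min-max normalization, per-feature entropy profiling with the
#' low-information relevance filter, entropy-weighted transformation,
#' additive fractal augmentation (when per-patient mask dimensions are
#' available; a no-op with a message otherwise), sigmoid adaptive
#' weighting and composition, greedy Pearson redundancy filtering
#' (priority = adaptive weight), ICC stability filtering (when replicates
#' are available), and optional cross-validated evaluation. Inputs are
#' never mutated; identical inputs and seed produce byte-identical
#' reports.
#'
#' @param features A [feature_matrix()] (raw scale; normalization is
#'   applied internally).
#' @param labels Optional 0/1 labels (default: those stored in
#'   `features`); required only when `evaluate = TRUE`.
#' @param replicates Optional [replicate_set()] of repeated extractions of
#'   the same (raw) features, used for ICC stability filtering.
#' @param fractal_dims Optional per-patient fractal dimensions (named
#'   vector or data frame from [patient_fractal_dimensions()]). When
#'   absent the augmentation stage is skipped (dimension 0 for every
#'   patient).
#' @param config A [serfe_config()].
#' @param evaluate Run classifier evaluation on the refined panel?
#'   Default `TRUE` when labels are available.
#' @return A `serfe_result`: list with `refined` (a `refined_set` whose
#'   matrix holds the surviving weighted features and whose `provenance`
#'   table records every feature's entropy, factor, weight and fate),
#'   `filter_report`, `eval_report` (or `NULL`), and `manifest` (stage-by-
#'   stage feature counts, config echo, seed).
#' @export
run_serfe <- function(features, labels = NULL, replicates = NULL,
                      fractal_dims = NULL, config = serfe_config(),
                      evaluate = NULL) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(config, "serfe_config"))
  labels <- labels %||% features$labels
  evaluate <- evaluate %||% !is.null(labels)
  initial <- feature_names(features)
  dropped <- data.frame(feature = character(0), reason = character(0),
                        statistic = numeric(0), stringsAsFactors = FALSE)

  norm <- min_max_normalize(features)
  profile <- tryCatch(
    estimate_entropy(norm, bins = config$entropy_bins,
                     floor = config$entropy_floor, alpha = config$alpha),
    serfe_error = function(e) serfe_abort(
      sprintf("entropy stage: %s", conditionMessage(e)), class(e)[1L]))

  rel <- relevance_filter(norm, profile)
  dropped <- rbind(dropped, rel$dropped)
  kept_profile <- profile[!profile$low_information, , drop = FALSE]
  n_post_entropy <- ncol(rel$matrix$values)

  transformed <- entropy_weight_transform(
    rel$matrix,
    structure(kept_profile, class = class(profile), bins = attr(profile, "bins"),
              alpha = attr(profile, "alpha"), H_max = attr(profile, "H_max"),
              floor = attr(profile, "floor")),
    alpha = config$alpha)

  if (is.null(fractal_dims)) {
    message("no masks/fractal dimensions supplied: fractal augmentation is a no-op (D_f = 0)")
    dims <- stats::setNames(rep(0, nrow(features$values)), patient_ids(features))
  } else if (is.data.frame(fractal_dims)) {
    dims <- stats::setNames(fractal_dims$D_f, fractal_dims$patient_id)
  } else {
    dims <- fractal_dims
  }
  augmented <- fractal_augment(transformed, dims, beta = config$beta)

  weights <- compute_adaptive_weights(augmented, gamma = config$gamma,
                                      score_fun = config$score_fun)
  refined <- compose_refined(augmented, weights)

  red <- redundancy_filter(refined$matrix,
                           threshold = config$redundancy_threshold,
                           priority = stats::setNames(weights$weight,
                                                      weights$feature))
  dropped <- rbind(dropped, red$dropped)
  n_post_redundancy <- ncol(red$matrix$values)

  stability_score <- NULL
  iccs <- NULL
  final_matrix <- red$matrix
  if (!is.null(replicates)) {
    stopifnot(inherits(replicates, "replicate_set"))
    iccs <- icc_estimate(rs_select(replicates, red$retained))
    stab <- stability_filter(iccs, threshold = config$icc_threshold)
    dropped <- rbind(dropped, stab$dropped)
    stability_score <- stab$stability_score
    if (length(stab$retained) == 0L)
      abort_degenerate("stability filter dropped every feature")
    final_matrix <- fm_select(red$matrix, stab$retained)
  }
  n_post_stability <- ncol(final_matrix$values)

  report <- assemble_filter_report(
    initial_features = initial,
    retained = feature_names(final_matrix),
    dropped = dropped,
    redundancy_rate = red$redundancy_rate,
    stability_score = stability_score,
    iccs = iccs,
    thresholds = list(entropy_floor = config$entropy_floor,
                      redundancy = config$redundancy_threshold,
                      icc = config$icc_threshold))

  prov <- data.frame(feature = initial, stringsAsFactors = FALSE)
  prov$H_bits <- profile$H_bits[match(initial, profile$feature)]
  prov$entropy_factor <- profile$factor[match(initial, profile$feature)]
  prov$weight <- weights$weight[match(initial, weights$feature)]
  drop_at <- dropped$reason[match(initial, dropped$feature)]
  prov$status <- ifelse(is.na(drop_at), "retained", drop_at)

  refined$matrix <- feature_matrix(
    final_matrix$values, labels = if (!is.null(labels)) labels else NULL)
  refined$provenance <- prov

  eval_report <- NULL
  if (evaluate) {
    if (is.null(labels))
      abort_validation("evaluation requested but no labels available")
    eval_report <- evaluate_classifiers(refined$matrix, labels = labels,
                                        config = config)
  }

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    n_patients = nrow(features$values),
    counts = list(initial = length(initial),
                  post_entropy = n_post_entropy,
                  post_redundancy = n_post_redundancy,
                  post_stability = n_post_stability),
    stages = c("normalize", "entropy_profile", "relevance_filter",
               "entropy_transform", "fractal_augment", "adaptive_weights",
               "compose", "redundancy_filter",
               if (!is.null(replicates)) "stability_filter",
               if (evaluate) "evaluate"),
    package_version = as.character(utils::packageVersion("serfe"))
  )
  counts <- unlist(manifest$counts)
  if (any(diff(counts) > 0))
    serfe_abort("manifest feature counts increased across filter stages",
                "serfe_internal_error")

  structure(list(refined = refined, filter_report = report,
                 eval_report = eval_report, manifest = manifest),
            class = "serfe_result")
}

#' @export
print.serfe_result <- function(x, ...) {
  cts <- x$manifest$counts
  cat(sprintf("<serfe_result> features %d -> %d (entropy) -> %d (redundancy) -> %d (stability)\n",
              cts$initial, cts$post_entropy, cts$post_redundancy,
              cts$post_stability))
  print(x$filter_report)
  if (!is.null(x$eval_report)) print(x$eval_report)
  invisible(x)
}

# --- JSON serialization (stable ordering, no timestamps) --------------------

filter_report_json <- function(report) {
  jsonlite::toJSON(unclass(report), dataframe = "columns", auto_unbox = TRUE,
                   digits = NA, null = "null", pretty = TRUE)
}

eval_report_json <- function(report) {
  out <- lapply(report$classifiers, function(r) {
    list(folds = r$folds, mean = as.list(r$mean), sd = as.list(r$sd),
         auc = r$auc, roc = r$roc)
  })
  jsonlite::toJSON(list(classifiers = out, fold_assignment = report$fold_assignment,
                        seed = report$seed, n = report$n),
                   dataframe = "columns", auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

manifest_json <- function(manifest) {
  jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write the pipeline reports to a directory
#'
#' Serializes the filter report, evaluation report (when present), run
#' manifest and refined feature table into `dir`. JSON output carries no
#' timestamps, so reruns with identical inputs and seed are byte-identical.
#'
#' @param result A `serfe_result` from [run_serfe()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_serfe_reports <- function(result, dir) {
  stopifnot(inherits(result, "serfe_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(filter_report = file.path(dir, "filter_report.json"),
             manifest = file.path(dir, "run_manifest.json"),
             refined = file.path(dir, "refined_features.csv"),
             provenance = file.path(dir, "feature_provenance.csv"))
  writeLines(filter_report_json(result$filter_report), paths[["filter_report"]])
  writeLines(manifest_json(result$manifest), paths[["manifest"]])
  write_feature_table(result$refined$matrix, paths[["refined"]])
  utils::write.csv(result$refined$provenance, paths[["provenance"]],
                   row.names = FALSE, quote = FALSE)
  scal <- data.frame(patient_id = names(result$refined$serfe_scalar),
                     serfe_scalar = unname(result$refined$serfe_scalar))
  utils::write.csv(scal, file.path(dir, "serfe_scalar.csv"),
                   row.names = FALSE, quote = FALSE)
  paths[["serfe_scalar"]] <- file.path(dir, "serfe_scalar.csv")
  if (!is.null(result$eval_report)) {
    paths[["eval_report"]] <- file.path(dir, "eval_report.json")
    writeLines(eval_report_json(result$eval_report), paths[["eval_report"]])
  }
  invisible(paths)
}
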