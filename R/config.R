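#' Pipeline configuration
#'
#' Bundles every tunable of the refinement pipeline with its default.
#'
#' @param alpha Exponent of the entropy weighting factor `(H_i/H_max)^alpha`;
#'   `alpha = 0` disables entropy weighting. Default 1.
#' @param beta Scale of the additive fractal augmentation `beta * D_f`;
#'   `beta = 0` disables augmentation. Default 0.1.
#' @param gamma Sensitivity of the sigmoid adaptive weight; larger values
#'   push weights toward a hard indicator around the mean score. Default 4,
#'   chosen so weights span roughly (0.1, 0.9) for typical score spreads on
#'   \[0, 1\]-scaled features.
#' @param entropy_bins Number of equal-width histogram bins on \[0, 1\] used
#'   for per-feature entropy estimation. Default 64.
#' @param entropy_floor Minimum per-feature entropy (bits) to survive the
#'   low-information relevance filter. Default 0.5.
#' @param redundancy_threshold Absolute Pearson correlation above which a
#'   feature is redundant with an already-retained one. Default 0.85.
#' @param icc_threshold Minimum intraclass correlation for a feature to be
#'   considered stable. Default 0.75.
#' @param cv_folds Number of stratified cross-validation folds. Default 5.
#' @param seed Integer seed driving every stochastic step. Default 1.
#' @param score_fun Patient-to-feature aggregation used for adaptive
#'   weighting scores: `"mean"` (default) or `"median"`.
#' @return An object of class `serfe_config`.
#' @export
serfe_config <- function(alpha = 1.0, beta = 0.1, gamma = 4.0,
                         entropy_bins = 64L, entropy_floor = 0.5,
                         redundancy_threshold = 0.85, icc_threshold = 0.75,
                         cv_folds = 5L, seed = 1L,
                         score_fun = c("mean", "median")) {
  score_fun <- match.arg(score_fun)
  cfg <- list(alpha = as.numeric(alpha), beta = as.numeric(beta),
              gamma = as.numeric(gamma), entropy_bins = as.integer(entropy_bins),
              entropy_floor = as.numeric(entropy_floor),
              redundancy_threshold = as.numeric(redundancy_threshold),
              icc_threshold = as.numeric(icc_threshold),
              cv_folds = as.integer(cv_folds), seed = as.integer(seed),
              score_fun = score_fun)
  validate_config(cfg)
  structure(cfg, class = "serfe_config")
}

validate_config <- function(cfg) {
  if (cfg$alpha < 0) abort_validation("alpha must be >= 0")
  if (cfg$beta < 0) abort_validation("beta must be >= 0")
  if (cfg$gamma <= 0) abort_validation("gamma must be > 0")
  if (cfg$entropy_bins < 2L) abort_validation("entropy_bins must be >= 2")
  if (cfg$entropy_floor < 0) abort_validation("entropy_floor must be >= 0")
  for (f in c("redundancy_threshold", "icc_threshold"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      abort_validation(sprintf("%s must lie in (0, 1]", f))
  if (cfg$cv_folds < 2L) abort_validation("cv_folds must be >= 2")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; keys absent from the file keep their defaults.
#'
#' @param path Path to a YAML file whose keys mirror [serfe_config()].
#' @param ... Overrides applied on top of the file values (CLI flags use
#'   this).
#' @return A `serfe_config`.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path) %||% list()
  known <- names(formals(serfe_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    abort_format(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  vals <- utils::modifyList(vals, list(...))
  do.call(serfe_config, vals)
}
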