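#' Sigmoid adaptive feature weights
#'
#' Scores each feature by the cohort mean (or median) of its transformed
#' values, `s_i`, and assigns the logistic weight
#' `W_i = 1 / (1 + exp(-gamma * (s_i - mu)))` where `mu` is the grand mean
#' of the per-feature scores. Weights lie strictly in (0, 1), equal 0.5
#' exactly when `s_i = mu`, and increase monotonically in `s_i`; growing
#' `gamma` pushes every weight away from 0.5 toward a hard indicator of
#' `s_i > mu`.
#'
#' @param matrix A [feature_matrix()] (typically the entropy-transformed,
#'   fractal-augmented panel).
#' @param gamma Positive sensitivity parameter. Default 4.
#' @param score_fun `"mean"` (default) or `"median"` patient aggregation.
#' @return An `adaptive_weights` data frame with columns `feature`, `score`,
#'   `weight`, and attributes `gamma`, `mu`.
#' @export
compute_adaptive_weights <- function(matrix, gamma = 4.0,
                                     score_fun = c("mean", "median")) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (gamma <= 0) abort_validation("gamma must be > 0")
  score_fun <- match.arg(score_fun)
  s <- switch(score_fun,
              mean = colMeans(matrix$values),
              median = apply(matrix$values, 2L, stats::median))
  mu <- mean(s)
  if (ncol(matrix$values) == 1L)
    warning("single-feature matrix: adaptive weight is 0.5 by construction",
            call. = FALSE)
  w <- stats::plogis(gamma * (s - mu))
  structure(
    data.frame(feature = feature_names(matrix), score = unname(s),
               weight = unname(w), stringsAsFactors = FALSE),
    class = c("adaptive_weights", "data.frame"),
    gamma = gamma, mu = mu, score_fun = score_fun
  )
}

#' Compose the refined feature set
#'
#' Applies the adaptive weights feature-wise: retained column `i` becomes
#' `W_i` times the input column, preserving a full per-patient feature set
#' for downstream classification. The literal weighted-sum scalar
#' `sum_i W_i * f_i(p)` is also emitted per patient as `serfe_scalar`, an
#' auditable one-number summary of the refined panel.
#'
#' @param matrix A [feature_matrix()] aligned with `weights`.
#' @param weights An `adaptive_weights` object from
#'   [compute_adaptive_weights()].
#' @return A `refined_set`: list with `matrix` (weighted features),
#'   `weights`, `serfe_scalar` (named per-patient vector), and `provenance`
#'   (filled by [run_serfe()]).
#' @export
compose_refined <- function(matrix, weights) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(weights, "adaptive_weights"))
  if (!identical(weights$feature, feature_names(matrix)))
    abort_alignment("adaptive weights do not match the matrix feature set")
  w <- weights$weight
  out <- sweep(matrix$values, 2L, w, "*")
  scalar <- as.numeric(matrix$values %*% w)
  structure(
    list(matrix = feature_matrix(out, labels = matrix$labels),
         weights = weights,
         serfe_scalar = stats::setNames(scalar, patient_ids(matrix)),
         provenance = NULL),
    class = "refined_set"
  )
}

#' @export
print.refined_set <- function(x, ...) {
  cat(sprintf("<refined_set> %d patients x %d weighted features\n",
              nrow(x$matrix$values), ncol(x$matrix$values)))
  invisible(x)
}

#' Export the weight audit table
#'
#' @param refined A `refined_set`.
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
write_weight_audit <- function(refined, path) {
  stopifnot(inherits(refined, "refined_set"))
  df <- if (!is.null(refined$provenance)) refined$provenance
        else as.data.frame(refined$weights)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
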