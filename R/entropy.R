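#' Per-feature Shannon entropy profile
#'
#' Estimates, for every feature of a \[0, 1\]-normalized matrix, the Shannon
#' entropy (in bits) of its across-patient distribution from an equal-width
#' histogram on \[0, 1\]. Probabilities are maximum-likelihood bin
#' frequencies (counts / n) with no smoothing, so constant features get an
#' entropy of exactly 0 bits — the degenerate behavior the low-information
#' filter relies on. The profile also carries the multiplicative weighting
#' factor `(H_i / H_max)^alpha`, where `H_max` is the largest per-feature
#' entropy in the panel: the most informative feature passes through the
#' weighting unchanged while lower-entropy features are shrunk toward zero.
#'
#' @param matrix A [feature_matrix()] normalized to \[0, 1\]
#'   (see [min_max_normalize()]).
#' @param bins Number of equal-width histogram bins. Default 64.
#' @param floor Entropy floor in bits; features below it are flagged
#'   low-information. Default 0.5.
#' @param alpha Exponent applied to `H_i / H_max`. Default 1.
#' @return An `entropy_profile`: data frame with columns `feature`,
#'   `H_bits`, `factor`, `low_information`, plus attributes `bins`, `alpha`,
#'   `H_max`.
#' @export
estimate_entropy <- function(matrix, bins = 64L, floor = 0.5, alpha = 1.0) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (nrow(matrix$values) < 2L)
    abort_validation("entropy estimation needs at least 2 patients")
  v <- matrix$values
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    abort_validation("matrix must be normalized to [0, 1] before entropy estimation")
  bins <- as.integer(bins)
  n <- nrow(v)
  H <- vapply(seq_len(ncol(v)), function(j) {
    idx <- pmax(pmin(base::floor(v[, j] * bins) + 1L, bins), 1L)
    p <- tabulate(idx, nbins = bins) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  H[apply(v, 2L, function(x) diff(range(x)) == 0)] <- 0
  H_max <- max(H)
  if (H_max == 0)
    abort_degenerate("all features are constant: entropy profile is degenerate (H_max = 0)")
  prof <- data.frame(
    feature = colnames(v),
    H_bits = H,
    factor = (H / H_max)^alpha,
    low_information = H < floor,
    stringsAsFactors = FALSE
  )
  structure(prof, class = c("entropy_profile", "data.frame"),
            bins = bins, alpha = alpha, H_max = H_max, floor = floor)
}

check_profile_alignment <- function(matrix, profile) {
  if (!identical(profile$feature, feature_names(matrix)))
    abort_alignment("entropy profile does not match the matrix feature set")
}

#' Entropy-weighted feature transform
#'
#' Multiplies feature `i` by `(H_i / H_max)^alpha`. With `alpha = 0` the
#' transform is the identity; the maximal-entropy feature is always left
#' unchanged. Applying the transform with exponents `a1` then `a2` (same
#' profile) equals a single application with `a1 + a2`.
#'
#' @param matrix The [feature_matrix()] the profile was computed from.
#' @param profile An `entropy_profile` from [estimate_entropy()].
#' @param alpha Exponent; defaults to the profile's own alpha.
#' @return A transformed [feature_matrix()].
#' @export
entropy_weight_transform <- function(matrix, profile, alpha = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(profile, "entropy_profile"))
  check_profile_alignment(matrix, profile)
  alpha <- alpha %||% attr(profile, "alpha")
  if (alpha < 0) abort_validation("alpha must be >= 0")
  fac <- (profile$H_bits / attr(profile, "H_max"))^alpha
  out <- sweep(matrix$values, 2L, fac, "*")
  res <- feature_matrix(out, labels = matrix$labels)
  res$entropy_factors <- stats::setNames(fac, profile$feature)
  res
}

#' Low-information relevance filter
#'
#' Drops the features flagged `low_information` in the entropy profile
#' (entropy below the floor, including exact-zero-entropy constants) and
#' records them with reason `"low_entropy"`.
#'
#' @param matrix A [feature_matrix()] aligned with `profile`.
#' @param profile An `entropy_profile`.
#' @return List with `matrix` (surviving features) and `dropped`
#'   (data frame: feature, reason, statistic = entropy in bits).
#' @export
relevance_filter <- function(matrix, profile) {
  stopifnot(inherits(profile, "entropy_profile"))
  check_profile_alignment(matrix, profile)
  drop <- profile$low_information
  if (all(drop))
    abort_degenerate("relevance filter would drop every feature (all below the entropy floor)")
  dropped <- data.frame(
    feature = profile$feature[drop],
    reason = rep("low_entropy", sum(drop)),
    statistic = profile$H_bits[drop],
    stringsAsFactors = FALSE
  )
  list(matrix = fm_select(matrix, profile$feature[!drop]), dropped = dropped)
}

#' Export an entropy profile for audit
#'
#' @param profile An `entropy_profile`.
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
write_entropy_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
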