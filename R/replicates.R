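#' Construct a replicate set
#'
#' Repeated feature extractions for test-retest stability analysis: a
#' patients x features x replicates array sharing patient and feature order
#' with a base [feature_matrix()]. Designs must be balanced (the same
#' number of replicates, at least 2, for every patient).
#'
#' @param base A [feature_matrix()].
#' @param replicate_values 3-way numeric array, dim = (patients, features,
#'   replicates >= 2), same patient/feature order as `base`.
#' @return An object of class `replicate_set`.
#' @export
replicate_set <- function(base, replicate_values) {
  stopifnot(inherits(base, "feature_matrix"))
  d <- dim(replicate_values)
  if (length(d) != 3L)
    abort_validation("`replicate_values` must be a 3-way array (patients x features x replicates)")
  if (d[1L] != nrow(base$values) || d[2L] != ncol(base$values))
    abort_alignment("replicate array dimensions do not match the base matrix")
  if (d[3L] < 2L)
    abort_validation("at least 2 replicates per patient are required")
  if (anyNA(replicate_values))
    abort_validation("replicate array contains missing values; balanced complete designs only")
  structure(list(base = base, replicate_values = replicate_values),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  d <- dim(x$replicate_values)
  cat(sprintf("<replicate_set> %d patients x %d features x %d replicates\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

# subset a replicate set to a feature subset (pipeline internal)
rs_select <- function(rs, features) {
  idx <- match(features, feature_names(rs$base))
  if (anyNA(idx)) abort_alignment("replicate set lacks some requested features")
  replicate_set(fm_select(rs$base, features),
                rs$replicate_values[, idx, , drop = FALSE])
}
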