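#' Construct a feature matrix
#'
#' The central container of the package: a numeric patients-by-features
#' matrix with unique patient identifiers as row names, unique feature names
#' as column names, and an optional binary class label per patient
#' (1 = positive class, e.g. glioblastoma; 0 = other). Missing values are
#' refused at construction time — upstream extraction problems must be fixed
#' at the source, not imputed, because silent imputation would corrupt the
#' entropy estimates the refinement pipeline relies on.
#'
#' @param values Numeric matrix, rows = patients, columns = features. Must
#'   carry complete `dimnames`.
#' @param labels Optional integer/numeric vector of 0/1 class labels, one per
#'   patient, in row order (or named by patient id).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_validation("`values` must be a numeric matrix")
  ids <- rownames(values)
  feats <- colnames(values)
  if (is.null(ids) || is.null(feats))
    abort_validation("`values` must have patient ids as rownames and feature names as colnames")
  if (anyDuplicated(ids))
    abort_format(sprintf("duplicate patient id: %s", ids[duplicated(ids)][1L]))
  if (anyDuplicated(feats))
    abort_format(sprintf("duplicate feature name: %s", feats[duplicated(feats)][1L]))
  if (ncol(values) < 1L)
    abort_validation("feature matrix must contain at least one feature")
  if (anyNA(values) || any(!is.finite(values)))
    abort_format("feature matrix contains missing or non-finite values; refusing to impute")
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[ids]
    if (length(labels) != nrow(values) || anyNA(labels))
      abort_validation("`labels` must provide one 0/1 value per patient")
    if (!all(labels %in% c(0, 1)))
      abort_validation("`labels` must be binary (0/1)")
    labels <- as.integer(labels)
    names(labels) <- ids
  }
  structure(
    list(values = values, labels = labels),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d patients x %d features%s\n",
    nrow(x$values), ncol(x$values),
    if (is.null(x$labels)) "" else
      sprintf(" (labels: %d positive / %d negative)",
              sum(x$labels == 1L), sum(x$labels == 0L))
  ))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

patient_ids   <- function(m) rownames(m$values)
feature_names <- function(m) colnames(m$values)

# subset columns, keeping labels and class
fm_select <- function(m, features) {
  feature_matrix(m$values[, features, drop = FALSE], labels = m$labels)
}

#' Read a feature table from CSV
#'
#' Expects a header row, patient identifiers in the first column, and one
#' numeric column per feature. An optional label column (binary 0/1) can be
#' split off into the `labels` slot. Malformed input is rejected with a
#' precise error — duplicated names, duplicated patient ids, and non-numeric
#' or empty cells (reported with row/column coordinates) are all fatal.
#'
#' @param path Path to a CSV file (comma separator, `.` decimal, UTF-8).
#' @param label_column Optional name of the column holding 0/1 class labels.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path, label_column = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 2L)
    abort_format("feature table needs a patient-id column plus at least one feature")
  header <- colnames(raw)
  if (anyDuplicated(header))
    abort_format(sprintf("duplicate column name in header: %s",
                         header[duplicated(header)][1L]))
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    abort_format(sprintf("duplicate patient id: %s", ids[duplicated(ids)][1L]))
  body <- raw[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    col <- trimws(body[[j]])
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | col == "")
    if (length(bad))
      abort_format(sprintf(
        "non-numeric or empty cell at row %d, column '%s' (value: '%s')",
        bad[1L], colnames(body)[j], col[bad[1L]]))
    vals[, j] <- num
  }
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% colnames(vals))
      abort_format(sprintf("label column '%s' not present", label_column))
    labels <- vals[, label_column]
    if (!all(labels %in% c(0, 1)))
      abort_format(sprintf("label column '%s' must be binary 0/1", label_column))
    vals <- vals[, setdiff(colnames(vals), label_column), drop = FALSE]
  }
  feature_matrix(vals, labels = labels)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: values are serialized with enough
#' digits that a read/write round trip reproduces them to better than 1e-12
#' relative error. When labels are present they are appended as a trailing
#' `label` column.
#'
#' @param matrix A [feature_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (ncol(matrix$values) == 0L)
    abort_validation("refusing to write a feature table with zero features")
  fmt <- function(x) sprintf("%.17g", x)
  df <- data.frame(patient_id = patient_ids(matrix),
                   apply(matrix$values, 2L, fmt),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("patient_id", feature_names(matrix))
  if (!is.null(matrix$labels)) df$label <- matrix$labels
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write feature table to %s", path))
  invisible(path)
}

#' Min-max normalize features to [0, 1]
#'
#' Maps every non-constant feature affinely onto \[0, 1\]; constant features
#' are mapped to 0 and recorded in the `constant_features` field. All
#' entropy-weighting stages assume this common range, so that a single
#' multiplicative entropy factor is scale-meaningful across features.
#' Idempotent: normalizing an already-normalized matrix is the identity.
#'
#' @param matrix A [feature_matrix()] with at least two patients.
#' @return A normalized [feature_matrix()] whose `constant_features` field
#'   names the flagged constant columns.
#' @export
min_max_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (nrow(matrix$values) < 2L)
    abort_validation("min-max normalization needs at least 2 patients")
  v <- matrix$values
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  rng <- hi - lo
  const <- rng == 0
  out <- sweep(v, 2L, lo, "-")
  out[, !const] <- sweep(out[, !const, drop = FALSE], 2L, rng[!const], "/")
  out[, const] <- 0
  res <- feature_matrix(out, labels = matrix$labels)
  res$constant_features <- feature_names(matrix)[const]
  res
}
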