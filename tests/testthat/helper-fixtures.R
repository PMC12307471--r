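# Shared fixture builders (all programmatic; no stored data).

fm_from <- function(..., ids = NULL, labels = NULL) {
  cols <- list(...)
  v <- do.call(cbind, cols)
  rownames(v) <- ids %||% sprintf("P%03d", seq_len(nrow(v)))
  serfe::feature_matrix(v, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_fm <- function(n, p, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n,
              dimnames = list(sprintf("P%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  serfe::feature_matrix(v)
}

# cuboid ROI fixture with arbitrary in-mask intensities laid along x
roi_from_values <- function(values, pad = 1L) {
  n <- length(values)
  d <- c(n + 2L * pad, 1L + 2L * pad, 1L + 2L * pad)
  intens <- array(0, d)
  mask <- array(0L, d)
  intens[pad + seq_len(n), pad + 1L, pad + 1L] <- values
  mask[pad + seq_len(n), pad + 1L, pad + 1L] <- 1L
  serfe::volume_roi(intens, mask)
}

# digitized ball mask of given voxel radius
ball_roi <- function(radius, spacing = c(1, 1, 1)) {
  g <- 2L * radius + 5L
  ax <- seq_len(g) - (g + 1) / 2
  dist <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  mask <- (dist <= radius) * 1L
  serfe::volume_roi(array(1, dim(mask)) * dist, mask, spacing = spacing)
}

# brute-force AUC: all-pairs concordance with half weight for ties
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
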