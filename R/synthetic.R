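#' Synthetic cohort specification
#'
#' Describes a cohort feature matrix with known ground truth, emulating the
#' statistical structure a refinement pipeline must handle: independent
#' informative features carrying a class mean shift, equicorrelated blocks
#' of redundant noise features, near-constant (low-information) spike
#' columns, unstable features with poor test-retest ICC, and independent
#' filler noise. Defaults mirror a typical single-site tumor cohort: 100
#' patients with a 57% positive-class fraction, 3 repeated extractions per
#' patient, stable features at ICC 0.9 and unstable ones at ICC 0.3.
#'
#' @param n_patients Number of patients. Default 100.
#' @param n_features Total number of features. Default 200.
#' @param n_informative Independent features shifted by `class_effect`
#'   between classes. Default 20.
#' @param n_redundant_blocks,block_size Number and size of equicorrelated
#'   noise blocks. Defaults 10 blocks of 5.
#' @param rho Within-block correlation in \[0, 1). Default 0.9.
#' @param class_effect Standardized mean difference on informative
#'   features. Default 1.
#' @param positive_fraction Positive-class fraction. Default 0.57.
#' @param n_low_info Near-constant spike columns (rare-event indicator
#'   columns whose entropy falls below typical floors). Default 10.
#' @param replicate_count Replicates per patient (>= 2). Default 3.
#' @param target_icc Population ICC of stable features, in (0, 1).
#'   Default 0.9.
#' @param n_unstable Number of filler features given `unstable_icc`
#'   instead. Default 30.
#' @param unstable_icc Population ICC of unstable features. Default 0.3.
#' @param seed Integer seed. Default 1.
#' @return A `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(n_patients = 100L, n_features = 200L,
                                  n_informative = 20L,
                                  n_redundant_blocks = 10L, block_size = 5L,
                                  rho = 0.9, class_effect = 1.0,
                                  positive_fraction = 0.57, n_low_info = 10L,
                                  replicate_count = 3L, target_icc = 0.9,
                                  n_unstable = 30L, unstable_icc = 0.3,
                                  seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               n_redundant_blocks = as.integer(n_redundant_blocks),
               block_size = as.integer(block_size), rho = rho,
               class_effect = class_effect,
               positive_fraction = positive_fraction,
               n_low_info = as.integer(n_low_info),
               replicate_count = as.integer(replicate_count),
               target_icc = target_icc, n_unstable = as.integer(n_unstable),
               unstable_icc = unstable_icc, seed = as.integer(seed))
  n_structured <- with(spec, n_informative + n_redundant_blocks * block_size + n_low_info)
  if (n_structured > spec$n_features)
    abort_validation("n_informative + blocks + n_low_info exceeds n_features")
  if (spec$rho < 0 || spec$rho >= 1) abort_validation("rho must lie in [0, 1)")
  for (f in c("target_icc", "unstable_icc"))
    if (spec[[f]] <= 0 || spec[[f]] >= 1)
      abort_validation(sprintf("%s must lie in (0, 1)", f))
  if (spec$positive_fraction <= 0 || spec$positive_fraction >= 1)
    abort_validation("positive_fraction must lie in (0, 1)")
  if (spec$replicate_count < 2L) abort_validation("replicate_count must be >= 2")
  n_filler <- spec$n_features - n_structured
  if (spec$n_unstable > n_filler)
    abort_validation("n_unstable exceeds the number of filler features")
  structure(spec, class = "synthetic_cohort_spec")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws the cohort described by a [synthetic_cohort_spec()]. Base features
#' are unit-variance Gaussians; redundant blocks share a common factor so
#' that the within-block correlation equals `rho`; informative features add
#' `class_effect` to positive patients; low-information columns are rare
#' 0/1 spikes. Replicates equal the base value plus homoscedastic Gaussian
#' within-subject noise with variance `(1 - ICC) / ICC` (between-subject
#' variance 1), the exact algebra under which the one-way population ICC
#' equals the target. Bit-reproducible given the spec seed.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return List with `features` (a labeled [feature_matrix()]),
#'   `replicates` (a [replicate_set()]), and `truth` (ground-truth record:
#'   informative, redundant blocks, low-information, unstable features,
#'   population ICC per feature, spec echo).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  p <- spec$n_features
  ids <- sprintf("P%04d", seq_len(n))

  n_pos <- round(n * spec$positive_fraction)
  labels <- integer(n)
  labels[sample(n, n_pos)] <- 1L

  nm_inf <- sprintf("inf_%02d", seq_len(spec$n_informative))
  nm_red <- unlist(lapply(seq_len(spec$n_redundant_blocks), function(b)
    sprintf("red_b%02d_f%d", b, seq_len(spec$block_size))))
  nm_low <- sprintf("lowinfo_%02d", seq_len(spec$n_low_info))
  n_filler <- p - length(nm_inf) - length(nm_red) - length(nm_low)
  nm_fill <- sprintf("noise_%03d", seq_len(n_filler))
  feats <- c(nm_inf, nm_red, nm_low, nm_fill)

  v <- matrix(0, n, p, dimnames = list(ids, feats))
  if (spec$n_informative > 0L)
    v[, nm_inf] <- matrix(stats::rnorm(n * spec$n_informative), n) +
      spec$class_effect * labels
  for (b in seq_len(spec$n_redundant_blocks)) {
    z <- stats::rnorm(n)
    cols <- sprintf("red_b%02d_f%d", b, seq_len(spec$block_size))
    v[, cols] <- sqrt(spec$rho) * z +
      sqrt(1 - spec$rho) * matrix(stats::rnorm(n * spec$block_size), n)
  }
  if (spec$n_low_info > 0L) {
    spikes <- matrix(stats::rbinom(n * spec$n_low_info, 1L, 0.05), n)
    spikes[1L, ] <- 1L    # guarantee non-constant columns
    v[, nm_low] <- spikes
  }
  if (n_filler > 0L)
    v[, nm_fill] <- matrix(stats::rnorm(n * n_filler), n)

  base <- feature_matrix(v, labels = labels)

  nm_unstable <- nm_fill[seq_len(spec$n_unstable)]
  icc_pop <- stats::setNames(rep(spec$target_icc, p), feats)
  icc_pop[nm_unstable] <- spec$unstable_icc
  sw2 <- (1 - icc_pop) / icc_pop        # sigma_b^2 = 1 on the base scale
  k <- spec$replicate_count
  reps <- array(0, dim = c(n, p, k), dimnames = list(ids, feats, NULL))
  for (r in seq_len(k))
    reps[, , r] <- v + matrix(stats::rnorm(n * p), n) *
      matrix(sqrt(sw2), n, p, byrow = TRUE)

  list(
    features = base,
    replicates = replicate_set(base, reps),
    truth = list(informative = nm_inf,
                 redundant_blocks = split(nm_red, rep(seq_len(spec$n_redundant_blocks),
                                                      each = spec$block_size)),
                 low_information = nm_low,
                 unstable = nm_unstable,
                 population_icc = icc_pop,
                 labels = stats::setNames(labels, ids),
                 spec = unclass(spec))
  )
}

#' Simulate a balanced replicate set with known variance components
#'
#' Direct generator for ICC calibration studies: subject effects with
#' variance `sigma_b2`, replicate noise with variance `sigma_w2`, so the
#' population ICC is `sigma_b2 / (sigma_b2 + sigma_w2)`.
#'
#' @param n_subjects,k Numbers of subjects and replicates.
#' @param sigma_b2,sigma_w2 Between- and within-subject variances.
#' @param n_features Number of independent features to draw. Default 1.
#' @param seed Integer seed.
#' @return A [replicate_set()].
#' @export
simulate_icc_replicates <- function(n_subjects, k, sigma_b2, sigma_w2,
                                    n_features = 1L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n_subjects))
  feats <- sprintf("f%03d", seq_len(n_features))
  subj <- matrix(stats::rnorm(n_subjects * n_features, sd = sqrt(sigma_b2)),
                 n_subjects, dimnames = list(ids, feats))
  arr <- array(0, dim = c(n_subjects, n_features, k),
               dimnames = list(ids, feats, NULL))
  for (r in seq_len(k))
    arr[, , r] <- subj + matrix(stats::rnorm(n_subjects * n_features,
                                             sd = sqrt(sigma_w2)), n_subjects)
  replicate_set(feature_matrix(subj), arr)
}

#' Generate a fractal phantom with known dimension
#'
#' Deterministic binary phantoms whose closed-form similarity dimension is
#' returned alongside, for use as oracles of the box-counting estimator:
#' a 1-pixel line (dimension 1), a filled square (2), a filled cube (3),
#' the Sierpinski carpet (log 8 / log 3) and the Sierpinski triangle
#' (log 3 / log 2).
#'
#' @param kind One of `"line"`, `"filled_square"`, `"filled_cube"`,
#'   `"sierpinski_carpet"`, `"sierpinski_triangle"`.
#' @param level_or_size Edge length for line/square/cube; recursion level
#'   for the Sierpinski phantoms (carpet edge `3^level`, triangle edge
#'   `2^level`).
#' @return List with `mask` (binary array), `dimension` (closed form),
#'   `kind`.
#' @export
generate_fractal_phantom <- function(kind = c("line", "filled_square",
                                              "filled_cube",
                                              "sierpinski_carpet",
                                              "sierpinski_triangle"),
                                     level_or_size) {
  kind <- match.arg(kind)
  s <- as.integer(level_or_size)
  out <- switch(kind,
    line = {
      m <- matrix(0L, s, s); m[s %/% 2L, ] <- 1L
      list(mask = m, dimension = 1)
    },
    filled_square = list(mask = matrix(1L, s, s), dimension = 2),
    filled_cube = list(mask = array(1L, c(s, s, s)), dimension = 3),
    sierpinski_carpet = {
      cell <- matrix(1L, 3L, 3L); cell[2L, 2L] <- 0L
      m <- matrix(1L, 1L, 1L)
      for (i in seq_len(s)) m <- kronecker(m, cell)
      list(mask = m, dimension = log(8) / log(3))
    },
    sierpinski_triangle = {
      cell <- matrix(c(1L, 1L, 1L, 0L), 2L, 2L)
      m <- matrix(1L, 1L, 1L)
      for (i in seq_len(s)) m <- kronecker(m, cell)
      list(mask = m, dimension = log(3) / log(2))
    })
  c(out, list(kind = kind))
}

# separable 3x3x3 box blur, `passes` iterations (edge-replicated)
smooth3d <- function(a, passes = 2L) {
  d <- dim(a)
  for (i in seq_len(passes)) {
    for (ax in 1:3) {
      lo <- seq_len(d[ax]); up <- pmin(lo + 1L, d[ax]); dn <- pmax(lo - 1L, 1L)
      a <- switch(ax,
        (a[dn, , , drop = FALSE] + a + a[up, , , drop = FALSE]) / 3,
        (a[, dn, , drop = FALSE] + a + a[, up, , drop = FALSE]) / 3,
        (a[, , dn, drop = FALSE] + a + a[, , up, drop = FALSE]) / 3)
    }
  }
  a
}

#' Generate a textured tumor-like volume
#'
#' Builds a blob-like connected mask by perturbing a centered sphere's
#' radius with smoothed Gaussian noise, and fills it with textured
#' intensities (baseline plus `texture_contrast` times a smoothed noise
#' field). With `texture_contrast = 0` the in-mask intensities are exactly
#' constant, exercising degenerate-ROI conventions. Deterministic given
#' `seed`; unit 1 mm spacing.
#'
#' @param seed Integer seed.
#' @param grid_size Cubic grid edge (>= 16). Default 32.
#' @param texture_contrast Intensity texture amplitude. Default 1.
#' @return A [volume_roi()].
#' @export
generate_tumor_volume <- function(seed = 1L, grid_size = 32L,
                                  texture_contrast = 1.0) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 16L) abort_validation("grid_size must be >= 16")
  set.seed(seed)
  g <- grid_size
  ax <- seq_len(g) - (g + 1) / 2
  dist <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  bump <- smooth3d(array(stats::rnorm(g^3), c(g, g, g)), passes = 3L)
  bump <- bump / max(abs(bump))
  r0 <- g / 4
  mask <- (dist <= r0 * (1 + 0.3 * bump)) * 1L
  tex <- smooth3d(array(stats::rnorm(g^3), c(g, g, g)), passes = 2L)
  intens <- 100 + texture_contrast * 20 * tex
  if (texture_contrast == 0) intens <- array(100, c(g, g, g))
  volume_roi(intens, mask, spacing = c(1, 1, 1))
}
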