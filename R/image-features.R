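#' Feature panel specification
#'
#' Controls the representative feature panel computed from a volume ROI:
#' first-order intensity statistics, gray-level co-occurrence (GLCM)
#' texture averaged over the 13 unique 3D directions, voxel-based shape
#' descriptors, and the spectral entropy of the in-mask intensity sequence.
#'
#' @param glcm_levels Gray-level count for GLCM quantization (>= 2).
#'   Default 16.
#' @param glcm_distances Integer voxel offsets (>= 1). Default 1.
#' @param histogram_bins Bins for the first-order histogram entropy.
#'   Default 64.
#' @param families Feature families to include.
#' @return A `feature_panel_spec` list.
#' @export
feature_panel_spec <- function(glcm_levels = 16L, glcm_distances = 1L,
                               histogram_bins = 64L,
                               families = c("first_order", "glcm", "shape",
                                            "spectral")) {
  if (glcm_levels < 2L) abort_validation("glcm_levels must be >= 2")
  if (any(glcm_distances < 1L)) abort_validation("glcm_distances must be >= 1")
  if (histogram_bins < 2L) abort_validation("histogram_bins must be >= 2")
  families <- match.arg(families, several.ok = TRUE)
  structure(list(glcm_levels = as.integer(glcm_levels),
                 glcm_distances = as.integer(glcm_distances),
                 histogram_bins = as.integer(histogram_bins),
                 families = families),
            class = "feature_panel_spec")
}

# the 13 unique 3D directions (one of each +/- pair)
glcm_directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  first <- apply(g, 1L, function(v) v[which(v != 0)[1L]] > 0)
  unname(g[first, , drop = FALSE])
}

#' First-order intensity statistics of a ROI
#'
#' Population moments of the in-mask intensities. Zero-variance ROIs
#' return skewness and (excess) kurtosis of 0 by convention, and a
#' histogram entropy of 0.
#'
#' @param roi A [volume_roi()].
#' @param spec A [feature_panel_spec()] (supplies `histogram_bins`).
#' @return Named numeric vector: mean, variance, skewness, kurtosis
#'   (excess), energy, entropy (bits), min, max, median, iqr, rms.
#' @export
first_order_features <- function(roi, spec = feature_panel_spec()) {
  x <- roi_values(roi)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  skew <- if (m2 == 0) 0 else mean((x - mu)^3) / m2^1.5
  kurt <- if (m2 == 0) 0 else mean((x - mu)^4) / m2^2 - 3
  ent <- if (diff(range(x)) == 0) 0 else {
    b <- spec$histogram_bins
    idx <- pmax(pmin(floor((x - min(x)) / diff(range(x)) * b) + 1L, b), 1L)
    p <- tabulate(idx, nbins = b) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  c(mean = mu, variance = m2, skewness = skew, kurtosis = kurt,
    energy = sum(x^2), entropy = ent,
    min = min(x), max = max(x), median = stats::median(x),
    iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
    rms = sqrt(mean(x^2)))
}

# quantize in-mask intensities to 1..levels by equal-width binning of the
# in-mask range; constant ROI maps to level 1
quantize_roi <- function(roi, levels) {
  x <- roi$intensities
  inm <- roi$mask > 0L
  v <- x[inm]
  q <- array(NA_integer_, dim = dim(x))
  if (diff(range(v)) == 0) {
    q[inm] <- 1L
  } else {
    q[inm] <- pmax(pmin(floor((x[inm] - min(v)) / diff(range(v)) * levels) + 1L,
                        levels), 1L)
  }
  q
}

#' Gray-level co-occurrence texture features
#'
#' Builds, for every distance and each of the 13 unique 3D directions, the
#' symmetric normalized co-occurrence matrix of quantized gray levels over
#' in-mask voxel pairs, and averages the derived features over directions
#' (and distances): energy, contrast, homogeneity, entropy (bits), and
#' correlation. A single-level ROI yields energy 1 and contrast 0 (one
#' co-occurrence cell), with correlation 0 by convention.
#'
#' @param roi A [volume_roi()] with at least 2 in-mask voxels.
#' @param spec A [feature_panel_spec()].
#' @return Named numeric vector: energy, contrast, homogeneity, entropy,
#'   correlation.
#' @export
glcm_features <- function(roi, spec = feature_panel_spec()) {
  if (sum(roi$mask) < 2L) abort_roi("GLCM needs at least 2 in-mask voxels")
  q <- quantize_roi(roi, spec$glcm_levels)
  dirs <- glcm_directions_3d()
  L <- spec$glcm_levels
  feats <- matrix(NA_real_, 0L, 5L)
  d3 <- dim(q)
  for (dist in spec$glcm_distances) {
    for (r in seq_len(nrow(dirs))) {
      off <- dirs[r, ] * dist
      src <- lapply(1:3, function(ax) {
        rng <- seq_len(d3[ax])
        rng[rng + off[ax] >= 1L & rng + off[ax] <= d3[ax]]
      })
      if (any(lengths(src) == 0L)) next
      a <- q[src[[1L]], src[[2L]], src[[3L]], drop = FALSE]
      b <- q[src[[1L]] + off[1L], src[[2L]] + off[2L], src[[3L]] + off[3L],
             drop = FALSE]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      cnt <- tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
      P <- matrix(cnt, L, L)
      P <- P + t(P)                        # symmetric pairs
      P <- P / sum(P)
      i <- row(P); j <- col(P)
      mu_i <- sum(i * P); mu_j <- sum(j * P)
      sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
      corr <- if (sd_i == 0 || sd_j == 0) 0 else
        (sum(i * j * P) - mu_i * mu_j) / (sd_i * sd_j)
      pz <- P[P > 0]
      feats <- rbind(feats, c(
        energy = sum(P^2),
        contrast = sum(P * (i - j)^2),
        homogeneity = sum(P / (1 + abs(i - j))),
        entropy = -sum(pz * log2(pz)),
        correlation = corr))
    }
  }
  if (nrow(feats) == 0L)
    abort_roi("no in-mask voxel pairs for any GLCM direction")
  stats::setNames(colMeans(feats),
                  c("energy", "contrast", "homogeneity", "entropy", "correlation"))
}

#' Voxel-based shape descriptors
#'
#' Volume is the voxel count times the voxel volume (mm^3); surface area
#' counts exposed voxel faces (mm^2) — exact for rectilinear shapes, biased
#' high for smooth ones; sphericity is `pi^(1/3) * (6 V)^(2/3) / A` (1 for
#' a perfect sphere, `(pi/6)^(1/3)` for a cube under face counting);
#' elongation is the ratio of the second to the first principal-axis
#' length of the in-mask voxel coordinates (1 for isotropic masks,
#' including the single-voxel degenerate case).
#'
#' @param roi A [volume_roi()].
#' @return Named numeric vector: volume_mm3, surface_mm2, sphericity,
#'   elongation.
#' @export
shape_features <- function(roi) {
  m <- roi$mask
  sp <- roi$spacing
  nvox <- sum(m)
  vol <- nvox * prod(sp)
  d <- dim(m)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- 0
  for (ax in 1:3) {
    padded <- array(0L, dim = d + c(ax == 1, ax == 2, ax == 3) * 2L)
    idx <- lapply(1:3, function(a) seq_len(d[a]) + (a == ax))
    padded[idx[[1]], idx[[2]], idx[[3]]] <- m
    shifted_up <- do.call(`[`, c(list(padded),
      lapply(1:3, function(a) seq_len(d[a]) + (a == ax) * 2L), list(drop = FALSE)))
    shifted_dn <- do.call(`[`, c(list(padded),
      lapply(1:3, function(a) seq_len(d[a])), list(drop = FALSE)))
    exposed <- sum(m & !shifted_up) + sum(m & !shifted_dn)
    area <- area + exposed * face_area[ax]
  }
  spher <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  coords <- which(m > 0L, arr.ind = TRUE)
  coords <- sweep(coords, 2L, sp, "*")
  elong <- if (nrow(coords) < 2L) 1 else {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
    if (ev[1L] == 0) 1 else sqrt(ev[2L] / ev[1L])
  }
  c(volume_mm3 = vol, surface_mm2 = area, sphericity = spher,
    elongation = elong)
}

#' Spectral entropy of the in-mask intensity sequence
#'
#' Shannon entropy (bits) of the normalized one-sided power spectrum of
#' the mean-subtracted in-mask intensities taken in fixed scan (array
#' index) order: conjugate frequency pairs are folded into single spectral
#' lines and the zero-frequency term is excluded. A constant ROI has no
#' non-DC power and returns 0; a pure sinusoid concentrates all power in
#' one spectral line (entropy 0); white noise approaches the flat-spectrum
#' maximum `log2(K)` over the `K` one-sided non-DC frequencies.
#'
#' @param roi A [volume_roi()].
#' @param bins Unused; kept for interface symmetry with histogram-based
#'   entropies.
#' @return Spectral entropy in bits.
#' @export
spectral_entropy <- function(roi, bins = NULL) {
  x <- roi_values(roi)
  if (length(x) < 2L || diff(range(x)) == 0) return(0)
  x <- x - mean(x)
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  h <- n %/% 2L
  # fold conjugate pairs: line k = |X_k|^2 + |X_{n-k}|^2 (Nyquist unpaired)
  pw <- vapply(seq_len(h), function(k)
    pw[k + 1L] + if (k < n - k) pw[n - k + 1L] else 0, numeric(1))
  tot <- sum(pw)
  if (tot <= 0) return(0)
  p <- pw / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the representative feature panel
#'
#' Runs every enabled feature family on the ROI and returns one named,
#' deterministically ordered feature row (`family_statistic` naming).
#' Bit-reproducible for a fixed ROI and spec.
#'
#' @param roi A [volume_roi()].
#' @param spec A [feature_panel_spec()].
#' @param patient_id Row name for the resulting matrix. Default "patient".
#' @return A one-row [feature_matrix()].
#' @export
extract_panel <- function(roi, spec = feature_panel_spec(),
                          patient_id = "patient") {
  out <- numeric(0)
  if ("first_order" %in% spec$families) {
    fo <- first_order_features(roi, spec)
    out <- c(out, stats::setNames(fo, paste0("fo_", names(fo))))
  }
  if ("glcm" %in% spec$families) {
    gl <- glcm_features(roi, spec)
    out <- c(out, stats::setNames(gl, paste0("glcm_", names(gl))))
  }
  if ("shape" %in% spec$families) {
    sh <- shape_features(roi)
    out <- c(out, stats::setNames(sh, paste0("shape_", names(sh))))
  }
  if ("spectral" %in% spec$families)
    out <- c(out, spec_entropy = spectral_entropy(roi))
  feature_matrix(matrix(out, nrow = 1L,
                        dimnames = list(patient_id, names(out))))
}
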