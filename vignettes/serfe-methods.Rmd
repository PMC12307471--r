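---
title: "Entropy-driven refinement of radiomics panels: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-driven refinement of radiomics panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serfe)
```

This vignette documents the statistical model behind `serfe`, the meaning
and defaults of its tunable parameters, what the synthetic generators do
and do not emulate, and the design decisions taken where the method left
genuine freedom. It states no empirical result that the package's tests or
`scripts/acceptance.R` do not themselves compute.

## The refinement model

`serfe` treats a radiomics study as a patients × features matrix
`F = {f_1, …, f_N}` (optionally with binary class labels and with repeated
extractions of the same features for stability analysis) and refines it in
six stages.

**Normalization.** Every feature is min-max mapped to [0, 1] before any
entropy computation. The entropy-weighted transform multiplies raw feature
values by a factor in [0, 1]; that multiplication is only scale-meaningful
when all features share a range, and a common range is what makes the
defaults for α, β and γ transferable across feature panels. Constant
columns map to 0 and are flagged. Missing cells are a hard error at load
time: silent imputation would distort the histogram entropies the first
filter depends on, so upstream extraction problems must be fixed upstream.

**Entropy-driven refinement.** The information content of feature *i* is
the Shannon entropy (bits) of its across-patient distribution,

$$H_i = -\sum_b p_b \log_2 p_b,$$

with `p_b` the maximum-likelihood frequencies of an equal-width histogram
on [0, 1]. Features with `H_i` below the entropy floor are discarded
(reason `low_entropy`), and each surviving column is multiplied by
`(H_i / H_max)^α` where `H_max` is the panel maximum. One modelling
ambiguity had to be resolved here: a set-level entropy cannot
differentiate features, while the method's purpose — letting features with
higher informational content retain greater significance — requires a
per-feature quantity. We therefore estimate `H_i` per feature and
normalize by the panel maximum, which is the only reading under which the
weighting discriminates features at all. The log base cancels in
`H_i / H_max`; bits are fixed for reporting. Probabilities are raw counts
with no smoothing, deliberately: smoothing would lift constant features
off `H = 0` and break the degenerate behavior the relevance filter relies
on.

**Fractal augmentation.** Tumor-margin complexity is summarized by the
box-counting dimension of the patient's binary mask: occupied-box counts
`N(ε)` on a fixed grid hierarchy anchored at the origin, and

$$D_f = \text{slope of } \log N(\varepsilon) \text{ against } \log(1/\varepsilon)$$

by least squares over all admissible scales (powers of two up to half the
smallest array dimension, at least four scales). Every feature value of
patient *p* is then shifted by `β · D_f(p)`. The object whose dimension is
taken is the *mask* — the one spatial input guaranteed to exist per
patient; a per-feature "feature map" alternative has no defined
construction for tabular input and is not implemented. The fixed-anchor
grid (no offset optimization, no scale windowing) keeps the estimator
deterministic; the fit R² is reported so poor scaling regimes are visible.
For CSV-only studies with no masks the stage is a logged no-op
(`D_f = 0`), keeping the pipeline usable on external tables.

**Local adaptive weighting.** Each feature's score `s_i` is the cohort
mean (configurably the median) of its transformed column; with
`μ = mean_i(s_i)` the grand mean over features, the weight is the logistic

$$W_i = \frac{1}{1 + e^{-\gamma (s_i - \mu)}} \in (0, 1),$$

exactly 0.5 at `s_i = μ` and monotone in `s_i`. Two readings were open and
are resolved as follows. First, `μ` is the grand mean of per-feature
scores, not a per-patient mean, because `W_i` must be a property of the
feature. Second, the final composition is applied as *element-wise column
re-scaling* `W_i · f_i(p)`: collapsing the panel to the literal weighted
sum `Σ_i W_i f_i(p)` would leave one scalar per patient and nothing for a
classifier to use. The literal scalar is still computed and emitted per
patient (`serfe_scalar`) as an auditable summary, and tests verify it
against a brute-force inner product.

**Redundancy filtering.** Features are scanned in descending adaptive
weight (ties broken lexicographically); a feature is dropped iff its
absolute Pearson correlation with an already-retained feature exceeds the
threshold (default 0.85). Keeping the higher-weight member of a correlated
pair is the choice consistent with prioritizing informative features; the
greedy scan guarantees (and a brute-force test verifies) that no retained
pair exceeds the threshold. Zero-variance features, whose correlation is
undefined, are logged as `zero_variance` and removed. The redundancy rate
is the percentage of candidates dropped at this stage; because the rate
depends on the set it is computed on, the filter report states the
candidate count alongside.

**Stability filtering.** From a balanced replicate set (same features
extracted across repeated scans), each feature's intraclass correlation

$$\mathrm{ICC} = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_w^2}$$

is estimated with the one-way random-effects ANOVA estimators
(`σ̂_w² = MS_within`, `σ̂_b² = (MS_between − MS_within)/k` clipped at 0,
0/0 → 0) — the standard sample counterpart of the population definition,
verified in tests against `aov` mean squares and by parameter recovery on
simulated variance components. ICC is computed on the *raw* replicate
values: the pipeline's transforms scale columns by constants (which ICC is
invariant to), so filtering on raw-scale ICC is equivalent and avoids
re-extracting transforms per replicate. Unbalanced designs are refused
rather than silently reweighted; ICC(2,1)/ICC(3,1) variants and
confidence intervals are out of scope. The stability score is the
percentage of candidate features with ICC at or above the threshold
(inclusive), computed before dropping. Features with ICC below threshold
drop with reason `unstable`.

**Evaluation.** Stratified k-fold cross-validation with three classifier
families: linear-kernel SVM (C = 1), 200-tree random forest, and k-NN
(k = 5, Euclidean distance on standardized features). Hyperparameters are
deliberately unremarkable and config-exposed — the package's claims are
about the feature pipeline, not classifier tuning. Per fold, feature
standardization is fit on the training split only; a test spikes the
held-out fold with an outlier and asserts the training statistics are
unchanged. ROC scores are the SVM decision margin, the forest's
positive-class vote fraction, and the neighbor vote fraction; AUC is the
rank-based (Mann–Whitney) probability that a random positive outranks a
random negative with ties counted ½, verified against an all-pairs
concordance count. Metrics are percentages; AUC is on [0, 1].

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | 1.0 | — | exponent of `(H_i/H_max)^α`; 0 disables entropy weighting |
| `beta` | 0.1 | — | scale of the additive `β·D_f` shift |
| `gamma` | 4.0 | — | sigmoid sensitivity; weights ≈ (0.1, 0.9) for typical score spreads on [0, 1] data |
| `entropy_bins` | 64 | bins | histogram resolution for `H_i` on [0, 1] |
| `entropy_floor` | 0.5 | bits | relevance cut-off; 0 keeps everything but exact constants |
| `redundancy_threshold` | 0.85 | \|r\| | correlation above which a pair is redundant |
| `icc_threshold` | 0.75 | ICC | stability cut-off (inclusive) |
| `cv_folds` | 5 | folds | stratified cross-validation |
| `seed` | 1 | — | drives all stochastic steps |

The two filter thresholds (0.85, 0.75) are the field's conventional
redundancy and test-retest stability cut-offs and are the pipeline's
reference operating point. The histogram resolution and entropy floor are
not prescribed by the method itself; 64 bins resolves cohort-scale
distributions without emptying most bins at n ≈ 100, and 0.5 bits sits
well below any feature with genuine spread while cleanly catching
rare-spike and constant columns. Both are config-exposed.

## What the synthetic generators emulate

`synthetic_cohort_spec()` describes a Gaussian cohort with exactly the
structures the filters target: independent unit-variance informative
features carrying a standardized mean shift *d* between classes;
equicorrelated blocks (common-factor construction, within-block
correlation ρ) of redundant noise; rare-event 0/1 spike columns whose
entropy falls below typical floors; and replicates formed as the base
value plus homoscedastic Gaussian within-subject noise with variance
`σ_w² = σ_b²(1 − ICC)/ICC` — the exact algebra under which the one-way
population ICC equals its target. Defaults are a 100-patient cohort with a
57% positive fraction, 200 features (20 informative, 10 redundant blocks
of 5 at ρ = 0.9, 10 low-information spikes, 30 unstable among the filler),
3 replicates, stable features at ICC 0.9 and unstable at 0.3. Stable
features sit at 0.9 rather than at the 0.75 threshold because a cut
exactly at the population value would misclassify half the stable features
through sampling noise alone; 0.9 is a realistic test-retest level for
robust radiomics features, and threshold-level recovery is exercised
separately by dedicated ICC calibration tests.

What the generator does *not* emulate: scanner physics (bias fields,
partial-volume effects), non-Gaussian and heavy-tailed feature marginals,
correlation between informativeness and instability, multi-site batch
structure, and any spatial coupling between the feature table and the
masks. Passing tests therefore demonstrate that the pipeline removes the
planted nuisance structures and recovers planted signal under a clean
statistical model — not that it attains any particular performance on
real MRI cohorts.

The fractal phantoms (line, filled square, filled cube, Sierpinski carpet
and triangle) have closed-form similarity dimensions and exact occupied-
cell recursions, giving the box-counting estimator independent oracles.
The tumor-volume generator (sphere with smoothed-noise radius
perturbation, textured interior) exercises the image-feature extractor,
including the constant-intensity degenerate case at
`texture_contrast = 0`.

## Numerical choices and degenerate inputs

- Histogram binning maps value `v` to bin `min(⌊v·bins⌋ + 1, bins)`, so
  1.0 falls in the top bin; indices are clamped against floating-point
  excursions at 0.
- Constant features: entropy 0, skewness/kurtosis 0, GLCM energy 1 and
  contrast 0, spectral entropy 0, elongation 1 for sub-2-voxel masks —
  all fixed conventions rather than errors, except where a whole matrix is
  degenerate (all-constant panels and all-dropped filters are errors).
- Spectral entropy uses the *one-sided* power spectrum (conjugate FFT
  pairs folded into single lines, DC excluded): a pure sinusoid is then
  exactly one spectral line (entropy 0) and white noise approaches
  `log2(K)` over the `K` one-sided frequencies. The two-sided alternative
  would assign a sinusoid 1 bit, conflating tonal and near-tonal ROIs.
- Surface area by voxel-face counting is exact for rectilinear shapes but
  converges to 1.5× the analytic area for smooth ones (the staircase
  bias), so digitized-ball sphericity converges to ≈ 2/3, not 1; cube
  sphericity `(π/6)^{1/3}` is exact. Tests assert these face-count closed
  forms rather than mesh-estimator values.
- GLCM matrices are accumulated over in-mask voxel pairs only,
  symmetrized, and normalized per direction; features are averaged over
  the 13 unique 3D directions that admit at least one pair.
- Stratified folds distribute each class's remainder over folds with a
  cyclic offset across classes, which keeps total fold sizes within one
  of each other while preserving per-class balance; assignments are
  deterministic given the seed.
- Feature tables are serialized with `%.17g`, so a write/read round trip
  reproduces doubles to better than 1e-12 relative error.

## Problem sizes used by the test and acceptance suites

Unit and property tests run on cohorts of 20–500 patients and panels of
10–200 features; ICC calibration uses 200 subjects × 3 replicates × 50
Monte-Carlo features per variance-component setting; fractal oracles use
phantoms up to 512² and 64³; classifier nulls and planted-signal checks
use 200-patient cohorts. These sizes make the whole suite complete in
well under a minute on a single core while leaving Monte-Carlo margins
comfortably inside the asserted bands. Chance-level checks on null
cohorts average over three independent cohort draws because a single
pooled null AUC at n = 200 has a standard error near 0.06 — one draw
alone cannot support a ±0.08 band.

## Known limitations

- The representative image panel (first-order, GLCM, shape, spectral
  entropy; 21 features) stands in for full IBSI batteries; GLRLM, GLSZM,
  NGTDM, wavelet and Gabor families are not implemented. The refinement
  stages are panel-agnostic and accept any external CSV table.
- Fractal augmentation adds the same `β·D_f(p)` to every feature of a
  patient; it encodes mask complexity, not feature-specific spatial
  structure.
- The adaptive weighting is unsupervised; labels never influence weights
  or filters, only the final evaluation.
- Redundancy filtering is greedy, not globally optimal: it guarantees a
  pairwise-decorrelated retained set but not the maximum-cardinality one.
- No DICOM ingestion, spatial resampling, orientation handling or
  bias-field correction: volumes are consumed as voxel grids with
  spacing, and preprocessing is assumed upstream.
- Multi-modality inputs (e.g. T1 and T2 panels) are treated as separate
  tables; no fusion logic is provided.
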