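# serfe

Entropy-driven refinement of radiomics feature panels for binary tumor
classification.

Radiomics pipelines extract hundreds to thousands of quantitative
descriptors (intensity statistics, co-occurrence texture, shape) from
segmented tumor volumes. Most of those features are redundant, unstable
across repeated scans, or nearly constant — and all three defects degrade
downstream classifiers. `serfe` refines a feature panel *at the table
level*: it takes any patients-by-features CSV (for example the output of an
IBSI-style extractor) and returns a compact panel of informative,
non-redundant, reproducible features, together with full per-feature
provenance and a cross-validated evaluation of the result.

## The method

Given a feature matrix with columns min-max normalized to [0, 1], the
pipeline applies, in order:

1. **Entropy-driven refinement.** Each feature's Shannon entropy
   H_i = −Σ_b p_b log₂ p_b is estimated from an equal-width histogram of
   its across-patient distribution. Features with H_i below a floor
   (default 0.5 bits) are discarded as low-information, and every surviving
   column is scaled by the factor (H_i / H_max)^α, so the most informative
   feature passes unchanged while low-entropy features are shrunk.
2. **Fractal augmentation.** The box-counting dimension D_f of each
   patient's binary tumor mask — the slope of log N(ε) against log(1/ε)
   over a fixed-anchor grid hierarchy — is added to that patient's features
   as β·D_f, injecting a morphological-complexity signal. Without masks the
   stage is a no-op.
3. **Local adaptive weighting.** Each feature's cohort score s_i (mean of
   the transformed column) is passed through the logistic weight
   W_i = 1 / (1 + e^{−γ(s_i − μ)}), μ the grand mean of scores, and columns
   are re-scaled by W_i. The literal weighted sum Σ_i W_i f_i(p) is also
   emitted per patient as an auditable scalar.
4. **Redundancy filtering.** Features are scanned in descending adaptive
   weight; a feature is dropped when its absolute Pearson correlation with
   any already-retained feature exceeds 0.85. The redundancy rate is the
   percentage dropped.
5. **Stability filtering.** From repeated extractions, each feature's
   intraclass correlation ICC = σ_b² / (σ_b² + σ_w²) is estimated by the
   one-way random-effects ANOVA; features with ICC < 0.75 are dropped, and
   the stability score is the percentage of candidates at or above the
   threshold.
6. **Evaluation.** Stratified 5-fold cross-validation of a linear SVM
   (C = 1), a 200-tree random forest and a 5-NN classifier, reporting
   balanced accuracy, precision, recall, F1 (per fold and mean, in %) and
   pooled out-of-fold ROC/AUC — with per-fold standardization fit on
   training folds only.

Synthetic generators (block-correlated cohorts with planted class effects
and controlled ICC, fractal phantoms with closed-form dimensions, textured
tumor volumes) make every stage testable offline, and a representative
NIfTI feature extractor (first-order, GLCM, shape, spectral entropy)
produces panels directly from image/mask pairs.

## Worked example

```r
library(serfe)

co  <- generate_cohort(synthetic_cohort_spec(seed = 7))
res <- run_serfe(co$features, replicates = co$replicates,
                 config = serfe_config(seed = 7))
res
#> <serfe_result> features 200 -> 190 (entropy) -> 152 (redundancy) -> 122 (stability)
#> <filter_report> 200 -> 122 features; redundancy rate 20.0%; stability score 80.3%
#> <eval_report> 100 patients, 5-fold CV (seed 7)
#>   svm            BA 96.9%  precision 98.5%  recall 96.4%  F1 97.3%  AUC 0.996
#>   random_forest  BA 97.6%  precision 96.8%  recall 100.0%  F1 98.3%  AUC 0.997
#>   knn            BA 93.5%  precision 93.5%  recall 96.5%  F1 94.9%  AUC 0.973

head(res$refined$provenance, 3)
#>   feature   H_bits entropy_factor    weight   status
#> 1  inf_01 5.036433      0.9122620 0.5442709 retained
#> 2  inf_02 5.173528      0.9370944 0.4663482 retained
#> 3  inf_03 5.151112      0.9330341 0.5128555 retained
```

The default synthetic cohort plants 20 informative features, 10 blocks of
5 highly correlated noise features, 10 near-constant columns and 30
low-ICC features among 200. The three filter stages remove exactly those
nuisance groups — the counts above show 10 dropped for low entropy, 38 as
redundant, 30 as unstable — while all 20 planted informative features
survive (`mean(co$truth$informative %in% res$filter_report$retained_features)`
is 1). The refined matrix then supports near-perfect cross-validated
classification of the planted class effect.

A command-line interface wraps the same functions:

```sh
SERFE_CLI=$(Rscript -e 'cat(system.file("cli", "serfe.R", package = "serfe"))')
Rscript $SERFE_CLI simulate --out-dir sim --seed 7
Rscript $SERFE_CLI refine   --features sim/features.csv --labels-column label \
                            --replicates-dir sim --out-dir out --seed 7
Rscript $SERFE_CLI extract  --image t1.nii.gz --mask tumor.nii.gz --out panel.csv
```

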