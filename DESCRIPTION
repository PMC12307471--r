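Package: serfe
Title: Spectral Entropic Radiomics Feature Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Entropy-driven refinement of radiomics feature panels for
    tumor classification. Implements per-feature Shannon-entropy weighting
    and low-information filtering, box-counting fractal dimension of tumor
    masks with additive feature augmentation, sigmoid-based local adaptive
    weighting, Pearson-correlation redundancy filtering, intraclass
    correlation (ICC) stability filtering from repeated extractions, and
    stratified cross-validated evaluation with SVM, random forest and
    k-nearest-neighbour classifiers. Includes a representative image
    feature extractor (first-order, co-occurrence texture, shape, spectral
    entropy) for NIfTI volumes with binary masks, and synthetic generators
    (correlated cohorts, replicate sets, fractal phantoms, textured tumor
    volumes) so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    class,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
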