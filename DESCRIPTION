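Package: deepcentroid
Title: Deep Cascade Ensembles of Nearest-Centroid Classifiers for Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary sample classification for high-dimensional, low-sample
    biomedical omics matrices (expression, methylation, cfDNA fragmentomics)
    using a deep cascade ensemble whose base learners are nearest-centroid
    classifiers fitted on randomly scanned feature subsets. Each cascade
    layer draws balanced with-replacement resamples, prunes base classifiers
    by out-of-bag Matthews correlation, feeds the surviving classifiers'
    signed centroid-distance scores (together with re-injected scanned
    features) to the next layer, and stops when out-of-bag performance no
    longer improves. Final predictions are majority votes of the last
    layer's classifiers; the vote fraction doubles as a positive-class
    probability. Includes prior-knowledge (GMT gene-set) and sliding-window
    scanning, paired multi-omics fusion, evaluation metrics (MCC, AUC,
    accuracy, F1), a repeated stratified cross-validation and independent
    validation harness, an ablation runner, feature-importance ranking, a
    synthetic omics data generator with planted informative features, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
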