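Package: msom
Title: Microscale Somatotopic Mapping of High-Gamma Activity on Dense Surface Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microscale motor mapping with high-density
    surface microelectrode (micro-ECoG) arrays. Converts multichannel voltage
    recordings into baseline-referenced broadband high-gamma (80-200 Hz) power
    via multitaper spectral estimation, quantifies movement-related modulation
    with a signed R-squared effect size, and performs family-wise-error-
    controlled inference on the electrode grid using threshold-free cluster
    enhancement (TFCE) with max-statistic permutation testing. Downstream
    analyses include extent-of-activation summaries and their timecourses,
    Dice-coefficient overlap of somatotopic activation masks, representational
    similarity analysis (Euclidean RDMs, metric MDS with Kruskal stress, Ward
    dendrograms), temporal-generalization decoding with sparse linear
    classifiers, and cross-participant spatial-gradient pooling with Fisher-z
    aggregation. A synthetic-data generator plants ground-truth footprints in
    1/f noise so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    ape,
    data.table,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
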