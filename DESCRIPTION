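Package: gcxgcalign
Title: Peak Matching Alignment for GCxGC-MS with Mass Spectral Similarity Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Peak matching alignment of comprehensive two-dimensional gas
    chromatography mass spectrometry (GCxGC-MS) peak lists. Implements five
    mass spectral similarity measures (cosine, Pearson, Spearman, partial and
    part correlation, including two-step rank-restricted variants that avoid
    covariance singularity), four retention time distance measures (Euclidean,
    Maximum, Manhattan, Canberra), and five alignment procedures (PAD, PAS,
    DW-PAS, SW-PAD, PAM with a mixture similarity score). Includes a
    benchmarking harness with TPR/FPR/PPV/F1 and ROC/AUC evaluation against
    ground-truth peak correspondences, and a synthetic peak list generator
    emulating sparse standard-mixture and dense biological sample regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
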