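Package: dynfc
Title: Dynamic and Static Functional-Connectivity Fingerprinting for
    Two-Group Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for whole-brain functional-connectivity fingerprinting of
    a patient group against controls from regional BOLD time series.  Computes
    static connectivity (full-series Fisher-z Pearson correlation) and dynamic
    connectivity (standard deviation of tapered sliding-window correlation
    series), classifies subjects with a leave-one-out cross-validated linear
    support-vector machine with nested univariate feature selection, assesses
    significance by whole-pipeline label permutation, and maps classifier
    weights back to signed discriminative networks, node degrees, and
    canonical-network fingerprints.  Includes a regime-switching latent-factor
    cohort simulator that plants dynamic-coupling or mean-coupling group
    differences with ground-truth edge annotation, so the full pipeline can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
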