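Package: cmipanel
Title: Cumulative Methylation Index Marker Panels for Cancer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating methylated-DNA marker panels
    for cancer detection from quantitative methylation-specific PCR data.
    Implements per-gene percent methylation, cumulative methylation index
    (CMI) scoring over gene panels, a three-stage rank-based marker-selection
    procedure (Mann-Whitney significance, normal-tissue background filter at
    the 75th percentile, carcinoma 75th-percentile ranking), empirical ROC
    analysis with locked-threshold train/test evaluation under a specificity
    floor, prevalence-adjusted predictive values, an agglomerative-clustering
    prescreen for candidate CpG loci, microsatellite-instability association
    tests, and a quantile-matched synthetic cohort generator so the whole
    workflow can be exercised without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
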