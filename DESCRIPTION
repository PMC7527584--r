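Package: sodiumap
Title: Quantitative Sodium MRI Mapping and Glioma Biomarker Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for absolute tissue sodium concentration mapping from
    sodium (23Na) MRI and for the downstream biomarker statistics used in
    glioma imaging studies. Implements double-angle transmit-field (B1)
    estimation with reciprocity-based receive correction, two-point
    calibration against external NaCl reference vials, compartment ROI
    statistics with normal-appearing white matter merging and whole-tumor
    fusion, semiquantitative edema hotspot detection, and a statistical
    battery (paired t-tests, Mann-Whitney U, Holm-Bonferroni step-down
    correction, ROC analysis with Youden cut-offs and bootstrap confidence
    intervals, precision-recall curves, volume-concentration correlation).
    Includes a synthetic phantom and cohort generator so the full pipeline is
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
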