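Package: mirpanel
Title: Diagnostic miRNA Biomarker Discovery from qPCR Panel Ct Profiles
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering diagnostic miRNA biomarkers
    from high-throughput qPCR (OpenArray-style) cycle-threshold panels of
    two-group cohorts, such as extracellular-vesicle miRNA profiles of
    peritoneal fluids. Implements Ct preprocessing (undetected-probe and
    low-detection-sample filtering, data-driven endogenous-control selection
    by interquartile range, delta-Ct normalization), per-probe differential
    expression with empirical-Bayes moderated t-statistics and
    Benjamini-Hochberg false-discovery-rate control, repeated random-split
    (3:2, 500 repetitions) univariate logistic evaluation of candidate
    markers with AUC, accuracy, sensitivity and specificity, a
    multi-database miRNA-target consensus vote, and a synthetic panel
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
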