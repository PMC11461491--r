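Package: etdiff
Title: Inter-Zonal Corneal Epithelial Thickness Differences for Keratoconus Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing zonal corneal epithelial thickness (ET) maps
    from anterior-segment OCT. Implements the inter-zonal ET difference
    statistic on a 41-zone, 7-mm polar grid (mean absolute difference between
    each zone and its edge-neighbours), the derived inferior-temporal and
    global screening parameters, and the full two-stage
    development/validation analysis used to evaluate them: per-zone ROC with
    data-driven zone selection, AUC with DeLong confidence intervals,
    sensitivity- and specificity-driven cut-off derivation, Mann-Whitney
    group comparisons with Bonferroni correction, Spearman correlation with
    tomographic indices, and intra-subject repeatability. A synthetic
    zonal-map cohort generator emulating healthy and keratoconic epithelial
    morphology makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
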