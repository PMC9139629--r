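Package: smrisk
Title: Secondary Malignancy Risk Modelling from Dose-Volume Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates radiation-induced secondary malignancy risk per organ
    from dose-volume histograms (DVHs) using two mechanistic models: the
    linear-quadratic competition model of Dasu (total and fatal risk) and the
    organ-equivalent-dose (OED) model of Schneider (OED and organ-specific
    cancer incidence). Provides DVH reading, validation and normalisation
    (cumulative or differential, relative or absolute volumes), organ
    parameter registries, a seeded generator of synthetic paired cohorts of
    thoracic-organ DVHs for three treatment modalities (3DCRT, IMRT and
    pencil-beam-scanned protons), and cohort-level paired comparison of
    modalities with exact Wilcoxon signed-rank tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
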