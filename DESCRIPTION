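Package: mirconsensus
Title: Consensus miRNA Marker Discovery for Neuroendocrine Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering microRNA markers that separate two tumor
    cohorts from bulk small-RNA expression matrices, built around the workflow
    used to distinguish peripancreatic paraganglioma (PGL) from pancreatic
    neuroendocrine tumors (PANNET). Reads and curates Xena-style
    log2(RPM+1) expression matrices and clinical metadata, applies the TCGA
    "-01" primary-tumor filter, computes t-SNE feature views with Procrustes
    alignment and convex-blend morphing between views, ranks miRNAs by a
    characteristic-direction vector estimated with L2-regularized logistic
    regression, intersects top-k rankings across demographically stratified
    re-analyses into a consensus marker set confirmed by one-way ANOVA, and
    validates markers across independently processed datasets via control-free
    percentile normalization. Includes a calibrated synthetic two-cohort
    generator so the whole pipeline is testable without data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rtsne,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    glmnet,
    vegan,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
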