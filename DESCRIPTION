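Package: methylmark
Title: Cell-Type-Specific CpG Marker Selection and Reference-Based
    Methylation Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for targeted DNA-methylation analysis of cell-type
    composition. Selects individual cell-type-specific CpG markers from
    labelled beta-value matrices by a stratified cross-validated
    dMean/sVar parabola-gate procedure scored with precision-recall AUC,
    computes the two-CpG FibroScore for fibroblast/MSC content, and
    estimates cell-type proportions from minimal CpG signatures by
    reference-based non-negative least squares. Includes a synthetic
    beta-value generator (pure profiles, planted markers, in-silico DNA
    mixtures with ground truth) so every stage can be tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
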