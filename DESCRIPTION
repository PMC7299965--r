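Package: stratomics
Title: Subtype-Stratified Multi-Omic Comparison of In Situ and Invasive Breast Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing ductal carcinoma in situ (DCIS) with invasive
    breast cancer (IBC) in a molecular-subtype-stratified manner across three
    genomic layers. Implements centroid-based intrinsic subtyping with
    ER-composition-balanced gene centering, bimodal receptor-status calling
    from marker-gene expression, mean-Z gene-expression signature scores,
    gene-level copy number and genomic instability summaries from segmented
    copy-number profiles, 450K-style beta-value quality control, imputation
    and per-gene first-principal-component methylation profiles, differential
    methylation with a joint FDR and effect-size filter, a windowed
    long-range-epigenetic-silencing score, and subtype-stratified group
    statistics. A fully specified synthetic multi-omic cohort generator makes
    the whole pipeline testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
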