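Package: comethdiff
Title: Differential Co-Methylation Network Analysis for Case-Control Methylation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-condition all-pairs Pearson co-methylation of
    gene-level Illumina 450K beta values, classifies control-to-case
    correlation changes on a fixed eight-interval scheme, extracts
    large-change gene pairs and their cross-disease intersection, and runs a
    subsampling repeatability experiment relating sample size to the
    stability of pairwise correlation estimates. Includes a synthetic
    beta-value generator with controlled per-condition correlation structure
    so every stage is testable without external data, plus readers for
    plain-TSV and GEO series-matrix beta tables and GPL13534-style
    probe-to-gene annotation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
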