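Package: hoxcode
Title: Tissue HOX Codes and Lineage Identity Scoring from Expression Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds tissue-of-origin reference profiles ("HOX codes") as
    per-tissue median expression vectors over the 39 human HOX genes,
    scores samples against them by Pearson correlation, and classifies
    lineage identity as kept or switched at a correlation threshold.
    Includes per-gene two-group comparison with Welch t-tests and
    Benjamini-Hochberg adjustment, semiquantitative
    immunohistochemistry H-score computation with Spearman correlation
    against ordinal tumor grade, readers and writers for delimited-text
    and GCT expression formats, correlation heatmaps, and a seeded
    synthetic-cohort generator for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    grid,
    pheatmap
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
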