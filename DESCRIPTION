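Package: trophoquant
Title: Per-Cell Immunofluorescence Quantification and Transcriptome
    Comparison for Trophoblast Stem-Cell Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two workflows common in trophoblast stem-cell
    biology. The imaging arm segments nuclei from a DAPI channel, measures
    per-nucleus marker intensity, thresholds positivity against an
    isotype-control image, and compares the fraction of marker-positive
    cells between treatment groups. The transcriptome arm filters count
    matrices against background, normalizes by median-of-ratios size
    factors, performs PCA, Spearman cross-type correlation and hierarchical
    clustering, selects differentially expressed genes by FDR and fold
    change, tests gene sets with the right-tailed Fisher's exact test split
    by direction of change, and computes delta-delta-Ct qPCR fold changes.
    Seeded synthetic-data generators with ground-truth sidecars make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ape,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
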