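Package: fixcurate
Title: Fixation-Aware Curation and Drought-Response Analysis of Plant
    Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating plant single-cell RNA-seq data generated
    from enzymatically digested (protoplast) tissue. Derives a
    cell-wall-digestion response gene signature from a factorial bulk
    RNA-seq design (digestion treatment by watering regime), scores every
    cell against that signature with expression-matched binned control
    genes, flags and removes cells that escaped transcriptome fixation,
    and profiles tissue-specific and dual (canonical abscisic-acid versus
    iron-starvation) mild-drought responses on the curated atlas. Includes
    a negative-binomial Wald and interaction likelihood-ratio test, profile
    clustering on Kendall correlation, per-cell module scoring, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    mclust,
    cluster,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
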