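Package: epiretscore
Title: Epigenomic Scoring of Retinal Degeneration from DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking retinal degeneration and treatment response
    from bisulfite-sequencing methylation data. Calls differentially
    methylated regions (DMRs) between sample groups with a Mann-Whitney U
    significance gate, derives a direction-labeled DMR signature from the
    intersection of disease-progression and treatment effects, and computes
    a per-sample epigenomic score by min-max normalization of region-mean
    beta values against early (P21) and late (P60) disease anchors, with the
    normalization reversed for hypomethylated regions. Includes scoring of
    plasma cell-free DNA restricted to tissue-detectable regions, CpG
    island/shore/shelf/open-sea context annotation, region- and pathway-set
    overlap statistics, hierarchical clustering helpers, and a seeded
    synthetic-cohort generator with ground-truth regions for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
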