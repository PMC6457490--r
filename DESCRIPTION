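Package: tilebind
Title: Binding-Region Calling and Rank Product Differential Expression
    for Two-Colour Tiling Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-colour, dye-swapped tiling
    microarray experiments contrasting two bacterial strains. Implements
    probe-level quality-flag filtering, dye-orientation correction, scale
    normalization and median centering, a strain-contrast enrichment
    caller with data-derived thresholding, single-linkage genomic
    clustering of enriched probes into binding regions, monophasic versus
    biphasic peak-shape classification, per-gene expression
    summarization, and Rank Product differential expression with
    permutation-estimated percentage-of-false-positives (pfp). Includes a
    ground-truthed synthetic data generator emulating a two-strain,
    dye-swapped, duplicate time-course design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
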