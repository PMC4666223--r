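Package: dmrrank
Title: Differentially Methylated Region Calling by Directional Rank Tests
    and Spatially Correlated P-Value Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from
    methylation-array beta-value matrices. For every unordered pair of
    sample groups, two one-sided Mann-Whitney U tests are computed per
    probe; probe p-values are combined over arbitrary genomic regions
    (tilings, promoters, or user-supplied BED intervals) with the
    Stouffer-Liptak method using a distance-binned autocorrelation
    estimate, and region p-values receive a one-step Sidak correction.
    Regions are summarized by the minimum, median and maximum per-probe
    change in methylation rate. Downstream, gene-linked region results
    feed a pre-ranked gene set enrichment analysis with permutation
    p-values and leading-edge overlap. Includes readers and writers for
    tab-separated methylation matrices, sample sheets, BED, GTF and GMT,
    detection p-value quality filtering, genome tiling and promoter
    extraction, a synthetic-data generator with spiked DMRs for
    end-to-end validation, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
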