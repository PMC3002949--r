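Package: cnvrmap
Title: Copy-Number Variant Region Maps from Multi-Caller CNV Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconciles per-individual copy-number variant (CNV) calls from
    two independent calling algorithms into concordant merged CNVs, clusters
    them across individuals into population-specific and cross-population
    copy-number variant region (CNVR) maps, annotates the maps against gene
    models and external interval catalogs, and computes population-difference
    statistics on per-individual CNV summaries. Ships a ground-truthed
    synthetic data generator emulating two-caller, two-population call sets
    (caller fragmentation, boundary jitter, direction-discordant calls,
    caller-private false positives) so that every pipeline stage is testable
    without access to raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
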