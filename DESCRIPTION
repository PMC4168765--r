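Package: intronret
Title: Intron-Retention Splice Variant Modelling and Truncated Receptor Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico characterization of intron-retention
    ("type II") splice variants of multi-exon genes, motivated by truncated
    interleukin-18 receptor alpha (IL18R1) transcripts. Builds spliced and
    intron-retained transcript models with exact transcript/genomic coordinate
    maps, continues the reading frame across the exon/intron boundary to
    predict truncated proteins and their novel C-terminal peptides, scans
    retained introns for polyadenylation signals and EST-supported
    transcription termination sites, predicts variant-discriminating PCR
    amplicons, characterizes transposable-element insertions (target-site
    duplications, oligo(dA) tails, substitution spectra against a consensus),
    and performs deterministic pairwise and progressive multiple alignment
    for cross-species comparison. A seeded synthetic-locus generator with
    ground-truth manifests makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
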