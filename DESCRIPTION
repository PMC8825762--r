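Package: orfeval
Title: Evaluation of Prokaryotic CDS Predictions Against a Reference Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores prokaryotic coding-sequence (CDS) prediction sets against a
    reference annotation using an in-frame, >=75%-coverage gene detection rule.
    Classifies every reference gene as perfectly matched, partially matched or
    missed, computes twelve primary comparison metrics (detection and perfect-match
    percentages, percentage differences of counts and lengths, median start/stop
    codon deviations, precision, recall, false discovery rate) plus secondary
    metric groups (GC content and length by match category, overlapping and short
    CDS counts, start/stop codon usage), ranks tools across genomes by summed
    metric ranks, aggregates predictions from multiple tools by deduplicated
    union, and provides GFF intersection and addition utilities. A built-in
    synthetic genome/annotation generator with a machine-readable truth ledger
    supports controlled perturbation experiments without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
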