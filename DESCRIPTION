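Package: metharc
Title: Single-Pass Pseudo-Genome Alignment and CpG Methylation Calling
    for Bisulfite and TAPS Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated workflow for DNA methylation sequencing data
    supporting both bisulfite and bisulfite-free (TAPS-like) chemistries.
    Builds a combined Watson+Crick converted pseudo-genome in 3-letter
    (all C to T) or 4-letter (CpG-context C to T only) mode so that reads
    are aligned in a single pass, restores alignments to original
    coordinates and strands, removes PCR duplicates, calls per-CpG
    methylation levels, estimates spike-in conversion rates, computes
    M-bias and other quality-control profiles, and renders a
    self-contained HTML report. A truth-tagged read simulator and a
    mapping-accuracy evaluator allow the whole pipeline to be exercised
    and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    data.table,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
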