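Package: plastedit
Title: RNA Editing Analysis for Plastid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises RNA editing in chloroplast
    transcriptomes. Builds per-position base pileups from RNA-read
    alignments against an annotated plastid genome, calls editing sites
    with a conversion-frequency threshold, annotates codon-level effects
    under the plastid (bacterial) genetic code, summarises editing by gene
    group and amino-acid transition, ranks gene expression by RPKM,
    screens intergenic spacers for low-identity hotspots by global
    alignment, and assesses editing-induced changes in rRNA secondary
    structure with a base-pair maximisation folder. Ships a synthetic
    quadripartite-plastome and read simulator with ground-truth tables so
    every stage is testable without external data, plus transcribed
    per-site and expression fixtures for desk reproduction of published
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
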