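Package: phagetu
Title: Transcriptional Landscape Inference for Lytic Bacteriophages from
    Stranded RNA-seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the transcriptional architecture of a lytic
    bacteriophage genome from strand-specific, multi-timepoint RNA-seq
    coverage. Transcription start and termination sites are called as
    sharp coverage steps, early (sigma-70-like) and late promoter motifs
    are learned from upstream windows and rescanned genome-wide with a
    training-recovery score threshold, Rho-independent terminators are
    called as GC-rich stem-loops followed by a polyT tract, counts are
    normalized by TMM/GeTMM with negative-binomial differential tests,
    and promoters, terminators and ORFs are assembled into early, late
    and dual transcription units. A synthetic-data module generates
    genomes and coverage with planted regulatory architecture so that
    every stage of the pipeline can be validated by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
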