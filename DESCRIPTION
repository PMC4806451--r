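Package: domainHMM
Title: Broad Domain and Narrow Peak Calling for ChIP-seq with a
    Two-State Gaussian Hidden Markov Model
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls both broad domains (e.g. H3K27me3, H3K36me3) and narrow
    peaks (e.g. transcription factor binding) in ChIP-seq data without mode
    switching.  Reads are MAPQ-filtered and counted into uniform genomic
    bins, control-normalized bin differences are truncated and modeled per
    chromosome with a two-state (enriched/depleted) hidden Markov model with
    Gaussian emissions fit by Baum-Welch EM using a scaled forward-backward
    recursion, and per-bin posterior probabilities are decoded into BED
    tracks color-coded by confidence.  Includes a peak-center refinement
    tool that replaces each enriched region with a fixed-width interval at
    its per-base coverage maximum, and synthetic-data generators (observation
    series from a specified HMM, and read-level BAM fixtures with planted
    domains and summits) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: ChIPSeq, PeakDetection, HiddenMarkovModel, Epigenetics, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
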