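Package: umishift
Title: UMI-Read Cluster Detection and Collapsing for UMI-Tagged RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and corrects the read-mapping-shift artefact in
    UMI-tagged RNA-Seq libraries. Reads sharing a unique molecular
    identifier (UMI) frequently map not to a single genomic coordinate but
    to a run of closely spaced coordinates, with most reads at a modal
    position and diminishing numbers up- and downstream. The package
    extracts UMIs from FASTQ reads, filters unique alignments from SAM/BAM,
    merges UMIs at each coordinate at Levenshtein distance one, chains
    coordinates sharing a UMI into UMI-read clusters under a configurable
    gap, collapses each cluster to a single molecule observation, and
    quantifies the artefact: pooled mapping-shift distributions, strictly-n
    spacing classes, cluster-size statistics, sequence-complexity trends
    (Shannon entropy and mutual information of modal reads), and gene-level
    UMI count tables with and without collapsing. A parameterized
    PCR-stutter simulator emits SAM plus ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
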