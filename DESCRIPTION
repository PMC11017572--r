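Package: pseudocheck
Title: Detecting Spurious Pseudogenes in Bacterial Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how sequencing coverage and base quality
    generate spurious pseudogene annotations in bacterial genome assemblies.
    Provides pseudogene-aware annotation comparison between near-identical
    genomes (fragment-based average nucleotide identity, coding-sequence
    clustering at a nucleotide similarity threshold, congruence statistics),
    a reference-based classifier of frameshift and internal-stop pseudogenes,
    a binomial regression model of per-CDS spurious-pseudogene probability as
    a function of read coverage and mean base quality, a 99th-percentile
    binomial filter for flagging anomalous assemblies against their nearest
    neighbor, and a synthetic-genome generator with coverage-dependent error
    injection for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
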