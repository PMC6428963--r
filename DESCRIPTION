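Package: wgpmap
Title: Whole-Genome-Profiling BAC Physical Map Simulation and Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for sequence-tag based (whole genome profiling, WGP)
    physical mapping of large, repeat-rich genomes from bacterial
    artificial chromosome (BAC) libraries.  Simulates repeat-rich genomes
    and BAC libraries, performs in-silico HindIII/MseI double digestion
    and fixed-length tag extraction from HindIII cut ends, builds
    three-dimensional row/column/split-box clone pooling designs,
    deconvolves pooled tag observations back to individual clones by the
    exactly-one-pool-per-dimension rule, and assembles tag-fingerprinted
    clones into contigs with a Sulston-score overlap test, FPC-style
    burying into SuperBACs, stepwise cutoff relaxation, consensus-band
    (CB) maps, and standard map statistics (N50, contigs per Mbp, map
    span).  Includes readers and writers for FASTA, BED, TSV and an
    FPC-style project file, plus a reproducible end-to-end pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    data.table,
    igraph,
    IRanges,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
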