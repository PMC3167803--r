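Package: dbgasm
Title: De Bruijn Graph Short-Read Assembly with Partitioned K-Mer Stores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale de novo short-read assembler built on a partitioned
    de Bruijn graph. Reads in FASTA or FASTQ are decomposed into canonical
    k-mers that are packed into 64-bit codes, deterministically partitioned
    with a linear congruential hash, and counted into sorted per-partition
    stores with prefix acceleration tables. Graph simplification removes
    low-frequency dead ends under an automatically estimated multiplicity
    threshold and clips tips shorter than 2k bases, then compacts the graph
    into unitigs. A twin-node sequence graph threads reads across unitigs,
    detects bubbles by Tour-bus style traversal, and merges near-identical
    parallel paths into contigs. Paired-end reads are mapped back to contigs
    to estimate per-library insert statistics, build reliable (>= 3 pair)
    scaffold links, and emit N-gapped scaffolds. Includes NG50/NG80 assembly
    statistics, a paired-read simulator with substitution errors and
    heterozygous-SNP haplotypes for end-to-end validation, and a command-line
    driver for the four pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
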