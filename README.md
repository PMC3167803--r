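# dbgasm

A desk-scale de novo short-read assembler for R, built on a partitioned de
Bruijn graph. It targets the short-insert Illumina regime — 36 bp reads,
~200 bp insert libraries — and assembles reads into unitigs, contigs and
N-gapped scaffolds, with simulation tooling to validate every stage against
a known truth.

## The method

A de Bruijn graph assembler replaces read overlap detection with exact
k-mer bookkeeping. Each k-mer (k odd, ≤ 31) is packed into a 64-bit base-4
code with A,C,G,T = 0,1,2,3; a k-mer and its reverse complement form one
double-stranded *k-molecule*, represented by the lexicographically smaller
strand (the *canonical* k-mer). The pipeline has four stages:

1. **K-mer counting.** Canonical k-mers are assigned to partitions by a
   linear congruential hash of the packed code — a k-mer and its reverse
   complement always co-locate — and counted into per-partition sorted
   vectors (16-bit saturating multiplicities). A prefix acceleration table
   over the top *r* bits (default 24) narrows each binary search from
   log N to about log(N/2^r).
2. **Graph construction and simplification.** An edge is created between
   two k-mers if and only if they are adjacent in at least one read; the
   eight possible neighbours are packed into one adjacency byte per node.
   Simplification removes dead-end k-mers with multiplicity below a
   threshold M estimated from the valley of the k-mer spectrum, clips tips
   shorter than 2k bases, and compacts every maximal 1-in/1-out chain into
   a unitig. Output is deterministic: byte-identical across runs and
   partition counts.
3. **Bubble merging and contigs.** Unitigs become twin-node pairs in a
   sequence graph; reads are threaded to create supported edges between
   nodes. Heterozygous SNPs and internal read errors produce *bubbles* —
   parallel paths between a shared source and sink — detected by Tour-bus
   style traversal and merged when the branches differ by at most 2 bases
   in length with ≥ 90% alignment identity. After node-level tip and
   low-coverage cleanup, linear runs are concatenated into contigs.
4. **Scaffolding.** Read pairs are mapped back onto contigs k-mer by
   k-mer; per-library insert medians and standard deviations are estimated
   from same-contig pairs; cross-contig pairs grouped by contig ends form
   links, reliable when supported by ≥ 3 pairs; a greedy ordering joins
   contig ends into simple paths emitted with gaps rendered as N runs.

Assemblies are summarized with NG50/NG80 statistics: order sequences by
length, accumulate from the largest until the total strictly exceeds 50%
(80%) of the reference genome size.

## Worked example

Simulate an error-free 30× paired-end library from a repeat-free 20 kb
genome and assemble it at k = 21:

```r
library(dbgasm)

cfg    <- sim_config(genome_length = 20000, coverage = 30, seed = 7)
genome <- simulate_genome(cfg, repeat_free_k = 21)
sim    <- simulate_pairs(genome, cfg)
reads  <- c(sim$pairs$read_1, sim$pairs$read_2)

res <- assemble(reads, k = 21)
res$log
#> # A tibble: 4 × 2
#>   stage    detail
#>   <chr>    <chr>
#> 1 kmers    k=21 n_parts=1 n_kmers=19980
#> 2 simplify M=2 low_freq_removed=0 tips_removed=0
#> 3 unitigs  n_unitigs=1 kept=1
#> 4 contigs  n_contigs=1 merged_bubbles=0

res$contigs[, c("contig", "length", "coverage")]
#> # A tibble: 1 × 3
#>   contig length coverage
#>    <int>  <int>    <dbl>
#> 1      1  20000     13.3
```

The 20,000 distinct 21-mers of the genome (19,980 interior ones observed)
collapse into a single unitig and a single contig reproducing the genome
exactly; its coverage, 13.3, is the mean k-mer multiplicity — about
30 × (36 − 21 + 1)/36, the expected k-mer depth of a 30× base coverage.
Summary statistics against the known genome size:

```r
assembly_summary(res$contigs, genome_size = 20000)
#> # A tibble: 1 × 7
#>   n_sequences total  ng50  ng80   max  mean median
#>         <int> <int> <dbl> <dbl> <int> <dbl>  <int>
#> 1           1 20000 20000 20000 20000 20000  20000
```

Lower-level stages are exposed individually — `count_kmers()`,
`add_read_linkages()`, `remove_low_frequency_dead_ends()`,
`remove_tips()`, `extract_chains()`, `build_sequence_graph()`,
`merge_bubbles()`, `finalize_contigs()`, `map_pairs()`,
`estimate_insert_stats()`, `build_links()`, `order_and_emit()` — and every
result is a tibble (stores and graphs have `tidy()`/`glance()` methods, a
k-mer spectrum `autoplot()` is provided):

```r
st <- count_kmers(reads, 21)
st
#> <kmer_store> k = 21, 1 partition(s), r = 24 (effective 24), 19,980 k-mers
head(tidy(st), 3)
#> # A tibble: 3 × 4
#>   kmer                  multiplicity adjacency partition
#>   <chr>                        <int>     <int>     <int>
#> 1 AAAAAAAGGCCACTCCTTTAG           18         0         0
#> 2 AAAAAACATTTCGCGCTTCAT            7         0         0
#> 3 AAAAAACCATCCCCGGTTACC            9         0         0
```

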