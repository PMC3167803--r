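---
title: "Assembly methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model behind `dbgasm`, the parameters that
matter, the design decisions taken where the method leaves room, and what
the bundled simulator does and does not emulate. It states no empirical
result beyond what the package's tests and `scripts/acceptance.R` compute.

## The double-stranded de Bruijn model

DNA is double stranded: a k-mer and its reverse complement are two
readings of one physical object, the *k-molecule*. `dbgasm` represents a
k-molecule by its canonical k-mer — the lexicographically smaller strand —
packed into a 64-bit integer, two bits per base, first base most
significant. That packing makes integer order equal lexicographic order,
so canonicalization is a single comparison. The 64-bit budget limits k to
31; the package additionally requires **k odd**, because an even k admits
palindromic k-mers equal to their own reverse complement, for which the
canonical strand (and hence adjacency orientation) is undefined. k is the
pipeline's one mandatory parameter; 21 is a sensible default for desk-scale
simulated genomes, and all other parameters default as described below.

### Partitioning

The k-mer store is split into `n_parts` partitions. The partition of a
k-mer is the LCG hash of its canonical code, reduced modulo `n_parts`:

    h(x) = ((6364136223846793005 * x + 1442695040888963407) mod 2^64) >> 33

The multiplier/increment pair is a standard well-mixed 64-bit LCG; the
constants are fixed constants of this implementation (any well-mixed
choice balances partitions equally well — the acceptance script measures
the max/min occupancy ratio across 16 partitions at 10^5 random 27-mers).
Because hashing follows canonicalization, a k-mer and its reverse
complement always land in the same partition. Partitioning is a semantic
device here: partitions are processed sequentially, and every externally
visible result is required (and tested) to be identical across partition
counts.

### The store

Each partition is a vector of records — canonical code, 16-bit saturating
multiplicity, 8-bit adjacency — sorted by code. Lookup is binary search,
narrowed by an acceleration table mapping each value of the top `r` bits
of the code (default `r = 24`, clamped to `2k`) to the contiguous record
range sharing that prefix, reducing the expected search to about
log(N/2^r). Removal tombstones records, which keeps the acceleration
table valid mid-pass; `compact_store()` reclaims slots between passes.
Partition contents round-trip through a small binary format (`.pshk`:
magic, version, k, r, count, 11-byte little-endian records) so stages can
run as separate processes.

## Graph construction

Adjacency is stored as one byte per record: the low nibble holds the four
possible right-extensions of the canonical strand (bit index = base code
of the following base), the high nibble the four left-extensions (bit
index = base code of the *complement* of the preceding base, which is the
same thing as a right-extension of the reverse strand). An edge is set
only when two k-mers are adjacent in at least one read — never by probing
all eight hypothetical neighbours, which can join k-mers that no read
supports. When an occurrence lies on the non-canonical strand the two
nibbles swap roles; the invariant, checked by a full scan in the tests, is
that every set bit has its orientation-corrected reciprocal bit set on the
neighbouring record.

## Simplification

**Low-frequency dead ends.** Sequencing errors produce k-mers that are
rare and hang off the graph as dead ends. The multiplicity threshold M is
estimated from the k-mer spectrum: smooth the multiplicity histogram with
a window-3 moving average, walk down from multiplicity 1, and take the
last point before the smoothed spectrum first rises toward the coverage
mode. A spectrum that rises from the start (clean data, no error mode)
yields the conservative fallback M = 2. Dead-end records with
multiplicity < M are removed round by round — removal exposes new dead
ends — until a round removes nothing. The first-rise rule rather than a
generic local-minimum scan is deliberate: on error-free spectra a
local-minimum scan can latch onto sampling noise in the falling tail past
the coverage mode and dismantle the whole graph.

**Tips.** A tip is a chain hanging off a branching node with a dead end on
the far side, the signature of read-end errors that survived the M filter.
Chains are walked from every dead end; a chain that terminates at a
branching node and spans fewer than 2k *bases* (at most k k-mers) is
removed and the branch repaired; longer chains are released. An isolated
linear chain — dead ends on both sides, no branch — is never a tip: it is
a short candidate contig. Tip length is counted in bases (kmer count
+ k − 1) since the 2k rule reads most naturally in sequence units.

**Chain extraction.** Unitigs are maximal chains in which every step has
one outgoing edge at the current k-mer and one incoming edge at its
successor. Extraction runs in two steps. Step 1 walks from every dead-end
k-mer; when the far terminal is also a dead end a rival walk from that end
exists, and the chain is kept only by the walk whose starting partition
index is ≤ the far partition's (ties: the smaller terminal code starts),
so each chain is emitted exactly once without coordination. Step 2 walks
all remaining k-mers in both directions, capturing chains between
branching nodes and pure cycles. Three determinism choices make output
byte-identical across runs and partition counts: cycles are broken at
their smallest canonical k-mer and emitted in the direction of the smaller
sequence (the natural "break where discovered" depends on partition
layout); chains are reported on the canonical strand; and results are
sorted before emission. Walks terminate at hairpin folds — a step onto the
very record being stood on, which is how a reverse-complement palindrome
in the genome presents — rather than traversing the k-molecule twice.

Each chain's coverage is its multiplicity sum divided by its sequence
length; chains below `min_coverage` (default 1, exposed as a flag) are
marked discarded. The default is deliberately permissive: the M filter and
tip clipping have already removed the error structure this filter would
otherwise chase.

## Bubble merging and contigs

Unitigs become nodes with twins (negative ids) in a sequence graph; edges
come from threading the original reads: two adjacent read k-mers in two
different nodes create or reinforce an oriented edge. No per-read mapping
is retained.

Bubbles — parallel paths between a shared source and sink, from
heterozygous SNPs, internal read errors, or joined tips — are found by a
Tour-bus style bounded traversal from each branching node, with priority
given by path length in bases and a search radius of `5k` bases from the
branch (bubbles from SNPs and errors are short; the bound applies to the
path walked so far, so a long reconvergence node is still seen). A
detected pair of internally disjoint paths is merged iff the two *branch
sequences* differ by ≤ 2 bases in length with ≥ 90% global-alignment
identity (matches / alignment length, unit costs). The branch sequence is
the full spelling of a branch's interior node chain with k−1 overlaps
collapsed; this definition is reverse-complement-symmetric, so both
traversal directions of one bubble see the same identity — a
marked-bases-only window is not, and would make the merge decision depend
on which side the traversal happened to start. The lower-coverage branch
is removed and its coverage folded into the winner. Only bubbles whose
losing branch carries no edges to outside nodes are merged; entangled
branches would need read re-mapping to resolve and are left to the
coverage filter.

Node coverage in this graph is the **mean k-mer multiplicity**
(multiplicity sum / k-mer count), not the per-base chain coverage: a short
node has far fewer k-mers than bases, and a per-base figure would make
every short node look shallow — in particular it would make freshly merged
SNP nodes fall under the low-coverage cutoff that is supposed to target
spurious joins. Final cleanup removes node-level tips (< 2k bases,
dead-ended, attached at a branch) and nodes below `min_coverage` (default
half the median node coverage — relative, so it adapts to simulated
depth), then concatenates maximal linear runs, collapsing k−1 overlaps.
Contigs ≥ 100 bases (the reporting filter, also applied to scaffolds and
summary statistics) are emitted on the canonical strand, sorted.

## Scaffolding

Mates are mapped to contigs k-mer by k-mer: a mate maps when ≥ 80% of its
k-mers hit one contig on one consistent diagonal; tied placements are
ambiguous and dropped. The 80%-consistent rule is this package's concrete
mapping criterion (exposed as `min_frac`). Only pairs with both mates
mapped are recorded.

Insert statistics (median, sd) come from pairs whose mates map to the same
contig, measured outer end to outer end; at least 100 such pairs are
required per library. Cross-contig pairs are grouped by the pair of contig
*ends* they connect — a forward mate points out of its contig's right end,
a reverse mate out of the left — which encodes relative orientation, so
contradictory orientations can never pool. Each pair contributes a gap
observation `median_insert − tail_a − tail_b`; a link is reliable with
≥ 3 supporting pairs. Single-read multi-node evidence is never used.

Ordering is greedy: links by descending support; accept a link when both
contig ends are free and the join does not close a cycle (the weakest link
of a cycle is rejected and logged). Accepted links form simple paths, each
emitted as one scaffold, gaps rendered as `max(1, round(gap))` Ns —
negative estimates (slightly overlapping contigs) clamp to a single N
rather than attempting an overlap merge, which keeps splitting scaffolds
at N-runs an exact inverse of emission. Each contig appears in exactly one
scaffold, once, in one orientation.

Note a geometric constraint worth knowing when designing scaffolding
experiments: with read length `rl`, a pair can only bridge a gap `g` when
its insert exceeds `g + 2·rl`. A 200-insert library with 36 bp mates
cannot span a 150-base gap; the scaffolding tests therefore use a
400 ± 40 insert library over such gaps.

## The simulator

`simulate_genome()` draws uniform random sequence, optionally
rejection-resampled until no (k−1)-mer repeats on either strand — the
condition under which the graph at k is a single branch-free path and
exact reconstruction is the right answer. `simulate_pairs()` draws
fragment positions uniformly, inserts from a rounded normal (defaults
200 ± 20; clamped to at least two read lengths), takes inward-facing 36 bp
mates from the fragment ends, applies i.i.d. substitution errors, and with
heterozygous sites set draws each fragment from one of two haplotypes with
equal probability. Fragments may overhang the molecule ends by up to one
read length and are truncated there: fragmentation of a linear molecule
produces fragments abutting its ends, and a hard in-range start rule would
leave the first and last read-length of the genome at a small fraction of
nominal depth, making terminal k-mers unsampleable at any realistic
coverage. Truth tables (fragment coordinates, haplotypes, SNP positions)
accompany every read set.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: indel errors, quality-value structure,
GC-dependent coverage bias, chimeric fragments, adapter read-through, and
repeat families longer than k−1 (beyond what random sequence contains).
Real genomes' repeat structure is the dominant difficulty this package's
desk-scale validation deliberately sidesteps.

## Problem sizes and numerical choices

The test suite and acceptance script run on 2–48 kb genomes at 20–40×
coverage — sizes chosen so the full suite exercises every stage, including
50 oracle-equivalence replicates against a naive single-table compaction,
in a few minutes on one core. At 30× with 36 bp reads and k = 21 the k-mer
depth is ~13×, so once in a few dozen simulations a position's k-mers go
entirely unsampled and the assembly honestly splits in two; the
fixed-seed tests sit in the typical case, and the acceptance script
reports whatever its seed produces.

Other numerical details: multiplicities saturate at 65535 (two bytes);
`r` is clamped to 2k so the acceleration table never exceeds the key
space; identity alignments use match +1, mismatch −1, gap −1 (unit
costs); all tie-breaks (duplicate chains, cycle break points, scaffold
walk starts, output order) resolve lexicographically so that repeated
runs are byte-identical.

## Known limitations

- k ≤ 31 (single 64-bit word) and odd; no quality-aware filtering
  (quality strings are parsed and discarded).
- Hairpin folds terminate chains rather than being assembled through;
  perfect palindromes of length ≥ k−1 truncate unitigs at the fold.
- Entangled bubbles (losing branch with outside edges) are not merged.
- The greedy scaffolder checks pairwise-link consistency only through its
  cycle rule; it does not re-estimate gaps jointly, and multi-library
  hierarchical scaffolding is out of scope.
- Partitioning is sequential-by-contract; no attempt is made to exploit
  it for parallel speed.
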