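#' Build de Bruijn graph linkages from read adjacency
#'
#' Sets adjacency bits on the canonical record of every k-mer occurrence: the
#' bit for the following base `S[i+k]` on the right, and the bit for the
#' complement of the preceding base `S[i-1]` on the left, with the two
#' nibbles swapped when the occurrence is on the non-canonical strand. A
#' linkage between two k-mers is created if and only if they are adjacent in
#' at least one read, so no spurious edges between coincidentally overlapping
#' k-mers arise. At read boundaries the extension base does not exist and no
#' bit is set; a read of length exactly `k` therefore contributes no linkage.
#'
#' Multiplicities are not touched here; they were fixed by [count_kmers()].
#' The reads must be the same set used for counting: a k-mer absent from the
#' store raises a consistency error.
#'
#' @param store a `kmer_store` built by [count_kmers()].
#' @param reads the reads (character vector or data frame), sanitized
#'   internally the same way as in counting.
#' @return the store, invisibly (modified in place).
#' @export
add_read_linkages <- function(store, reads) {
  stopifnot(inherits(store, "kmer_store"))
  reads <- sanitize_read(as_read_vector(reads))
  cpp_add_linkages(store$ptr, reads)
  invisible(store)
}

#' Check adjacency symmetry of the whole store
#'
#' Every set edge bit must have its orientation-corrected reciprocal bit set
#' on the neighbouring record. Holds after linkage construction and after
#' every simplification pass; full-scan check intended for test scale.
#'
#' @param store a `kmer_store`.
#' @return `TRUE` or `FALSE`.
#' @export
check_edge_symmetry <- function(store) {
  stopifnot(inherits(store, "kmer_store"))
  cpp_check_edge_symmetry(store$ptr)
}

#' Estimate the minimum multiplicity threshold M
#'
#' K-mer spectra of shotgun reads are bimodal: sequencing errors produce a
#' mode of low-multiplicity k-mers near 1, true genomic k-mers a mode near
#' the k-mer coverage depth. `M` is taken as the multiplicity at the first
#' local minimum of the smoothed histogram (moving average, window 3)
#' between the two modes; k-mers below `M` that dangle as dead ends are
#' treated as errors. When the histogram has no interior minimum (no
#' separate coverage peak), the conservative fallback is `M = 2`.
#'
#' @param x a `kmer_store`, or a histogram: a tibble with columns
#'   `multiplicity` and `count` (as from [kmer_histogram()]).
#' @return a single integer threshold.
#' @export
estimate_m <- function(x) {
  h <- if (inherits(x, "kmer_store")) kmer_histogram(x) else as_tibble(x)
  if (!all(c("multiplicity", "count") %in% names(h)))
    abort("histogram needs `multiplicity` and `count` columns")
  if (nrow(h) == 0) abort("empty multiplicity histogram")
  maxm <- max(h$multiplicity)
  dens <- numeric(maxm)
  dens[h$multiplicity] <- h$count
  if (maxm < 3) return(2L)
  # moving average, window 3, partial at the edges
  sm <- vapply(seq_len(maxm), function(i) {
    w <- max(1, i - 1):min(maxm, i + 1)
    mean(dens[w])
  }, numeric(1))
  # walk down from the error mode; the valley is the last point before the
  # smoothed spectrum first rises toward the coverage mode. A spectrum that
  # rises from the start (no error mode) has no interior minimum.
  for (m in 2:maxm) {
    if (sm[m] > sm[m - 1]) return(as.integer(max(2L, m - 1L)))
  }
  2L
}

#' Remove low-frequency dead-end k-mers
#'
#' Round by round, removes every record that is a dead end (no edges on at
#' least one side) with multiplicity below `m`, clearing the matching
#' adjacency bits on its surviving neighbours. Removal exposes new dead
#' ends, so rounds repeat until one removes nothing. With `m = NULL` the
#' threshold is estimated from the store's multiplicity histogram
#' ([estimate_m()]).
#'
#' @param store a `kmer_store` with linkages built.
#' @param m multiplicity threshold; k-mers with multiplicity `< m` qualify.
#' @return the store, invisibly; attributes `"removed"`, `"rounds"` and
#'   `"m"` report the pass.
#' @export
remove_low_frequency_dead_ends <- function(store, m = NULL) {
  stopifnot(inherits(store, "kmer_store"))
  if (is.null(m)) m <- estimate_m(store)
  res <- cpp_remove_low_freq_dead_ends(store$ptr, as.integer(m))
  attr(store, "removed") <- res$removed
  attr(store, "rounds") <- res$rounds
  attr(store, "m") <- as.integer(m)
  invisible(store)
}

#' Clip short tips
#'
#' A tip is a chain of k-mers hanging off a branching node with a dead end
#' on the far side, typically left by sequencing errors near read ends.
#' Starting from every dead-end k-mer the chain is extended base by base;
#' when it terminates at a branching node and spans fewer than `2k` bases
#' (chain of at most `k` k-mers), it is removed and the branching node's
#' adjacency repaired; chains of `2k` bases or more are released. An
#' isolated linear chain with dead ends on both sides is never a tip: it is
#' a candidate contig. The pass repeats until no removable tip remains.
#'
#' @param store a `kmer_store` after the low-frequency pass.
#' @return the store, invisibly; attributes `"tips_removed"` and
#'   `"kmers_removed"` report the pass.
#' @export
remove_tips <- function(store) {
  stopifnot(inherits(store, "kmer_store"))
  res <- cpp_remove_tips(store$ptr)
  attr(store, "tips_removed") <- res$tips_removed
  attr(store, "kmers_removed") <- res$kmers_removed
  invisible(store)
}

#' Extract linear chains (unitigs) from the simplified graph
#'
#' Two-step compaction. Step 1 walks from every dead-end k-mer in one
#' direction, extending while the current k-mer has a single outgoing edge
#' and the successor a single incoming edge. When the far terminal is itself
#' a dead end, a rival walk from that end exists; the chain is kept by the
#' walk whose starting partition index is the smaller (ties broken by the
#' smaller terminal code), so each chain is emitted exactly once. Step 2
#' walks every remaining k-mer in both directions, which captures chains
#' between branching nodes and pure cycles; a cycle is broken at its
#' smallest canonical k-mer and emitted once as a linear sequence, making
#' the output independent of partition count and traversal order.
#'
#' Each chain's coverage is the sum of its k-mer multiplicities divided by
#' its sequence length; chains below `min_coverage` are flagged as discarded
#' (`kept = FALSE`). Sequences are reported on the canonical strand (the
#' smaller of the sequence and its reverse complement) and sorted, so the
#' result is byte-identical across runs and partition counts.
#'
#' @param store a simplified `kmer_store`.
#' @param min_coverage minimum chain coverage to keep (default 1).
#' @return tibble with `unitig`, `sequence`, `length`, `kmer_count`,
#'   `mult_sum`, `coverage`, `kept`; attribute `k`.
#' @export
extract_chains <- function(store, min_coverage = 1) {
  stopifnot(inherits(store, "kmer_store"))
  ch <- cpp_extract_chains(store$ptr)
  out <- tibble(sequence = ch$sequence,
                kmer_count = as.integer(ch$kmer_count),
                mult_sum = ch$mult_sum) %>%
    mutate(length = nchar(.data$sequence),
           coverage = .data$mult_sum / .data$length,
           kept = .data$coverage >= min_coverage) %>%
    arrange(.data$sequence) %>%
    mutate(unitig = row_number()) %>%
    select("unitig", "sequence", "length", "kmer_count", "mult_sum",
           "coverage", "kept")
  attr(out, "k") <- store$k
  out
}

#' Write kept unitigs to FASTA
#'
#' Headers carry coverage and length, e.g. `>unitig_17 cov=28.4 len=512`.
#'
#' @param chains tibble from [extract_chains()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_unitigs <- function(chains, path) {
  kept <- chains[chains$kept, , drop = FALSE]
  ids <- sprintf("unitig_%d cov=%.1f len=%d", kept$unitig, kept$coverage,
                 kept$length)
  write_fasta(setNames(kept$sequence, ids), path)
}
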