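#' Count canonical k-mers into a partitioned store
#'
#' Decomposes reads into k-mers, canonicalizes each one (a k-mer and its
#' reverse complement are the same k-molecule and are counted once), assigns
#' it to a partition by the deterministic LCG hash of its canonical code, and
#' builds per-partition vectors of records sorted by code. Each record holds
#' the canonical code, a 16-bit multiplicity (saturating at 65535) and an
#' 8-bit adjacency mask, initially zero. A prefix acceleration table over the
#' most significant `r` bits of the code (clamped to `2k`) narrows later
#' binary searches to the records sharing that prefix.
#'
#' The store is an external pointer: simplification functions modify it in
#' place and return it invisibly for chaining.
#'
#' @param reads character vector of reads, or a data frame with a `sequence`
#'   column. Reads are sanitized (non-ACGT to `A`) before counting.
#' @param k k-mer length (odd, <= 31).
#' @param n_parts number of partitions.
#' @param r acceleration-table prefix width in bits (default 24).
#' @return a `kmer_store` object.
#' @examples
#' st <- count_kmers(c("ACGT", "ACGT"), k = 3)
#' tidy(st)
#' @export
count_kmers <- function(reads, k, n_parts = 1, r = 24) {
  k <- check_k(k)
  reads <- sanitize_read(as_read_vector(reads))
  n_parts <- as.integer(n_parts)
  if (n_parts < 1) abort("`n_parts` must be >= 1")
  r <- as.integer(r)
  if (r < 1 || r > 32) abort("`r` must be between 1 and 32")
  ptr <- cpp_store_build(reads, k, n_parts, r)
  new_kmer_store(ptr, k, n_parts, r)
}

new_kmer_store <- function(ptr, k, n_parts, r) {
  structure(list(ptr = ptr, k = as.integer(k), n_parts = as.integer(n_parts),
                 r = as.integer(r)),
            class = "kmer_store")
}

#' @export
print.kmer_store <- function(x, ...) {
  info <- cpp_store_info(x$ptr)
  cat(sprintf(
    "<kmer_store> k = %d, %d partition(s), r = %d (effective %d), %s k-mers\n",
    info$k, info$n_parts, info$r, info$r_effective,
    format(info$n_alive, big.mark = ",")))
  invisible(x)
}

#' @describeIn count_kmers number of live records in the store.
#' @param store a `kmer_store`.
#' @export
store_size <- function(store) {
  stopifnot(inherits(store, "kmer_store"))
  cpp_store_info(store$ptr)$n_alive
}

#' Tidy a k-mer store into a tibble of records
#'
#' @param x a `kmer_store`.
#' @param ... unused.
#' @return tibble with columns `kmer` (canonical string), `multiplicity`,
#'   `adjacency` (8-bit mask) and `partition`, sorted by k-mer.
#' @method tidy kmer_store
#' @export
tidy.kmer_store <- function(x, ...) {
  rec <- cpp_store_records(x$ptr)
  tibble(kmer = cpp_decode(rec$code, x$k),
         multiplicity = rec$multiplicity,
         adjacency = rec$adjacency,
         partition = rec$partition) %>%
    arrange(.data$kmer)
}

#' @method glance kmer_store
#' @export
glance.kmer_store <- function(x, ...) {
  info <- cpp_store_info(x$ptr)
  tibble(k = info$k, n_parts = info$n_parts, r = info$r,
         r_effective = info$r_effective, n_kmers = info$n_alive,
         n_slots = info$n_slots)
}

#' Look up k-mers in a store
#'
#' Lookups canonicalize the query first, restrict the binary search to the
#' acceleration-table range of the code's prefix, and return the record (or
#' absence) per query. `method = "linear"` performs a full scan instead and
#' exists as the reference implementation for testing: the two methods agree
#' on every probe.
#'
#' @param store a `kmer_store`.
#' @param kmers character vector of k-mers or a `kmer_code` object.
#' @param method `"accelerated"` (default) or `"linear"`.
#' @return tibble with `kmer`, `present`, `multiplicity`, `adjacency`
#'   (`NA` for absent k-mers).
#' @export
kmer_lookup <- function(store, kmers, method = c("accelerated", "linear")) {
  stopifnot(inherits(store, "kmer_store"))
  method <- match.arg(method)
  codes <- as_codes(kmers, store$k)
  res <- if (method == "accelerated") cpp_store_lookup(store$ptr, codes)
         else cpp_store_lookup_linear(store$ptr, codes)
  tibble(kmer = cpp_decode(codes, store$k),
         present = !is.na(res$multiplicity),
         multiplicity = res$multiplicity,
         adjacency = res$adjacency)
}

as_codes <- function(kmers, k) {
  if (inherits(kmers, "kmer_code")) {
    if (attr(kmers, "k") != k) abort("k-mer length does not match the store")
    unclass_code(kmers)
  } else {
    cpp_encode(sanitize_read(as.character(kmers)), k)
  }
}

#' Remove k-mer records from a store
#'
#' Records are tombstoned: subsequent lookups return absent, and a later
#' [compact_store()] reclaims the slots. Removing an absent k-mer is a no-op,
#' so removal is idempotent. When `clear_neighbors = TRUE` the adjacency bits
#' of surviving neighbours that pointed at the removed record are cleared as
#' well (the graph-simplification passes always do this).
#'
#' @param store a `kmer_store`.
#' @param kmers k-mers to remove (character or `kmer_code`).
#' @param clear_neighbors also repair neighbour adjacency bits.
#' @return the store, invisibly; the number removed is in attribute
#'   `"removed"`.
#' @export
kmer_remove <- function(store, kmers, clear_neighbors = FALSE) {
  stopifnot(inherits(store, "kmer_store"))
  n <- cpp_store_remove(store$ptr, as_codes(kmers, store$k), clear_neighbors)
  attr(store, "removed") <- n
  invisible(store)
}

#' @describeIn kmer_remove drop tombstoned slots and rebuild the
#'   acceleration tables.
#' @export
compact_store <- function(store) {
  stopifnot(inherits(store, "kmer_store"))
  cpp_store_compact(store$ptr)
  invisible(store)
}

#' Multiplicity histogram of a store
#'
#' @param store a `kmer_store`.
#' @return tibble with columns `multiplicity` and `count`, ascending.
#' @export
kmer_histogram <- function(store) {
  stopifnot(inherits(store, "kmer_store"))
  m <- cpp_store_mults(store$ptr)
  if (length(m) == 0) return(tibble(multiplicity = integer(), count = integer()))
  tb <- table(m)
  tibble(multiplicity = as.integer(names(tb)), count = as.integer(tb))
}

#' Write one partition of a store to a binary k-mer file
#'
#' The `.pshk` format: magic `"PSHK"`, a version byte, one byte each for `k`
#' and `r`, a little-endian 8-byte record count, then one 11-byte record per
#' canonical k-mer (8-byte code, 2-byte multiplicity, 1-byte adjacency, all
#' little-endian). The round trip through [read_kmer_file()] is bit-exact;
#' truncated or foreign files raise a format error naming the offending
#' offset.
#'
#' @param store a `kmer_store`.
#' @param partition 0-based partition index.
#' @param path output file path (conventional suffix `.pshk`).
#' @return `path`, invisibly.
#' @export
write_kmer_file <- function(store, partition, path) {
  stopifnot(inherits(store, "kmer_store"))
  cpp_write_pshk(store$ptr, as.integer(partition), path)
  invisible(path)
}

#' @describeIn write_kmer_file read a partition file back into a tibble of
#'   records (attributes `k` and `r` carry the header fields).
#' @export
read_kmer_file <- function(path) {
  res <- cpp_read_pshk(path)
  out <- tibble(kmer = cpp_decode(res$code, res$k),
                multiplicity = res$multiplicity,
                adjacency = res$adjacency)
  attr(out, "k") <- res$k
  attr(out, "r") <- res$r
  out
}

#' @describeIn write_kmer_file write every partition to
#'   `file.path(dir, sprintf("%s_p%03d.pshk", prefix, part))`.
#' @param dir,prefix output directory and file-name prefix.
#' @export
write_kmer_files <- function(store, dir, prefix = "kmers") {
  stopifnot(inherits(store, "kmer_store"))
  paths <- file.path(dir, sprintf("%s_p%03d.pshk", prefix, seq_len(store$n_parts) - 1))
  for (p in seq_along(paths)) cpp_write_pshk(store$ptr, p - 1L, paths[p])
  invisible(paths)
}

#' Rebuild a partitioned store from k-mer partition files
#'
#' Records are re-distributed by the canonical hash, so the result is
#' independent of how records were split across the input files.
#'
#' @param paths `.pshk` files.
#' @param n_parts partition count of the rebuilt store (default: one per
#'   input file).
#' @param r acceleration prefix bits (default: the value stored in the
#'   first file).
#' @return a `kmer_store`.
#' @export
store_from_kmer_files <- function(paths, n_parts = length(paths), r = NULL) {
  stopifnot(length(paths) >= 1)
  parts <- lapply(paths, cpp_read_pshk)
  k <- parts[[1]]$k
  if (any(vapply(parts, function(p) p$k, 0L) != k))
    abort("k-mer files disagree on k")
  if (is.null(r)) r <- parts[[1]]$r
  code <- do.call(cbind, lapply(parts, function(p) p$code))
  mult <- unlist(lapply(parts, function(p) p$multiplicity))
  adj <- unlist(lapply(parts, function(p) p$adjacency))
  ptr <- cpp_store_from_records(k, as.integer(n_parts), as.integer(r),
                                code, as.integer(mult), as.integer(adj))
  new_kmer_store(ptr, k, n_parts, r)
}
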