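#' Sanitize a read to the A/C/G/T alphabet
#'
#' Uppercases the input and converts every non-A/C/G/T character to `A`.
#' Reads are always retained whole, never discarded, so downstream k-mer
#' counting sees every read at full length.
#'
#' @param x character vector of reads (any characters, any case).
#' @return character vector of the same lengths containing only `A`, `C`,
#'   `G`, `T`.
#' @examples
#' sanitize_read("ACNGT")  # "ACAGT"
#' @export
sanitize_read <- function(x) {
  x <- toupper(as.character(x))
  gsub("[^ACGT]", "A", x)
}

new_kmer_code <- function(raw_mat, k) {
  structure(raw_mat, k = as.integer(k), class = "kmer_code")
}

#' Pack k-mers into 64-bit base-4 codes
#'
#' Bases A, C, G, T are assigned the values 0, 1, 2, 3 and packed with the
#' first base most significant, so that integer order on codes equals
#' lexicographic order on the strings. A 64-bit code limits k to 31; this
#' package additionally requires k to be odd so that no k-mer equals its own
#' reverse complement.
#'
#' @param seq character vector of k-mer strings, each of length `k`.
#' @param k the k-mer length (odd, between 1 and 31).
#' @return a `kmer_code` object (one code per input string).
#' @examples
#' as.numeric(kmer_encode("ACGT", 4))  # 27
#' as.numeric(kmer_encode("TTT", 3))   # 63
#' @export
kmer_encode <- function(seq, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 31)
    abort("`k` must be a single integer between 1 and 31")
  new_kmer_code(cpp_encode(as.character(seq), as.integer(k)), k)
}

#' Decode packed k-mer codes back to strings
#' @param code a `kmer_code` object.
#' @return character vector of k-mer strings.
#' @export
kmer_decode <- function(code) {
  stopifnot(inherits(code, "kmer_code"))
  cpp_decode(unclass_code(code), attr(code, "k"))
}

#' Reverse complement of packed k-mer codes
#'
#' An involution: `kmer_revcomp(kmer_revcomp(x))` equals `x`.
#'
#' @param code a `kmer_code` object.
#' @return a `kmer_code` object.
#' @export
kmer_revcomp <- function(code) {
  stopifnot(inherits(code, "kmer_code"))
  k <- attr(code, "k")
  new_kmer_code(cpp_revcomp(unclass_code(code), k), k)
}

#' Canonical form of packed k-mer codes
#'
#' The canonical k-mer is the lexicographically smaller of a k-mer and its
#' reverse complement; it is the stored representative of the k-molecule
#' (the double-stranded pair). `kmer_canonical()` is idempotent and
#' strand-invariant.
#'
#' @param code a `kmer_code` object.
#' @return a `kmer_code` object of canonical codes.
#' @export
kmer_canonical <- function(code) {
  stopifnot(inherits(code, "kmer_code"))
  k <- attr(code, "k")
  new_kmer_code(cpp_canonical(unclass_code(code), k), k)
}

#' Deterministic partition of a k-mer
#'
#' Hashes the canonical code with a fixed 64-bit linear congruential hash
#' (`h(x) = ((a x + c) mod 2^64) >> 33` with a = 6364136223846793005,
#' c = 1442695040888963407, constants of this implementation) and reduces it
#' modulo `n_parts`. A k-mer and its reverse complement always land in the
#' same partition, since canonicalization precedes hashing.
#'
#' @param code a `kmer_code` object.
#' @param n_parts number of partitions (>= 1).
#' @return integer vector of 0-based partition ids in `[0, n_parts)`.
#' @export
kmer_partition <- function(code, n_parts) {
  stopifnot(inherits(code, "kmer_code"))
  if (!is.numeric(n_parts) || length(n_parts) != 1 || n_parts < 1)
    abort("`n_parts` must be a single integer >= 1")
  cpp_partition_of(unclass_code(code), attr(code, "k"), as.integer(n_parts))
}

#' Enumerate the k-mers of a read
#'
#' Returns one row per k-mer window, in read order: the 0-based start
#' position, the canonical k-mer (decoded), and whether the observed strand
#' already was the canonical strand (needed to orient adjacency when building
#' the graph). A read shorter than k yields zero rows.
#'
#' @param read a single read (sanitized; see [sanitize_read()]).
#' @param k k-mer length.
#' @return tibble with columns `pos`, `kmer`, `is_canonical`.
#' @export
enumerate_kmers <- function(read, k) {
  k <- check_k(k)
  read <- sanitize_read(as.character(read)[1])
  e <- cpp_enumerate(read, k)
  tibble(pos = e$pos,
         kmer = cpp_decode(e$code, k),
         is_canonical = e$is_canonical)
}

unclass_code <- function(code) {
  m <- unclass(code)
  attr(m, "k") <- NULL
  m
}

#' @export
length.kmer_code <- function(x) ncol(unclass(x))

#' @export
as.character.kmer_code <- function(x, ...) kmer_decode(x)

#' @export
as.double.kmer_code <- function(x, ...) {
  v <- cpp_code_to_number(unclass_code(x))
  if (attr(x, "k") > 26)
    warning("codes for k > 26 exceed double precision; values are approximate")
  v
}

#' @export
`[.kmer_code` <- function(x, i) {
  new_kmer_code(unclass_code(x)[, i, drop = FALSE], attr(x, "k"))
}

#' @export
`==.kmer_code` <- function(e1, e2) {
  stopifnot(inherits(e1, "kmer_code"), inherits(e2, "kmer_code"))
  m1 <- unclass_code(e1); m2 <- unclass_code(e2)
  if (ncol(m1) == ncol(m2)) {
    colSums(m1 == m2) == 8L
  } else {
    kmer_decode(e1) == kmer_decode(e2)
  }
}

#' @export
print.kmer_code <- function(x, ...) {
  k <- attr(x, "k")
  n <- length(x)
  cat(sprintf("<kmer_code> k = %d, n = %d\n", k, n))
  show <- min(n, 10L)
  if (show > 0) cat(" ", paste(head(kmer_decode(x), show), collapse = " "), "\n")
  if (n > show) cat("  ...\n")
  invisible(x)
}
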