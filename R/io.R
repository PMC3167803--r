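#' Read FASTA or FASTQ files
#'
#' Thin wrappers over the Biostrings readers: multi-line FASTA, CRLF line
#' endings and gzip compression are handled, FASTQ quality strings are
#' parsed and discarded. Malformed records raise the reader's format error.
#'
#' @param path input file (plain or gzip).
#' @return tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- Biostrings::readBStringSet(path, format = "fasta")
  tibble(id = names(x), sequence = unname(as.character(x)))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  check_fastq_shape(path)
  x <- Biostrings::readBStringSet(path, format = "fastq")
  tibble(id = names(x), sequence = unname(as.character(x)))
}

# a 4-line-record sanity check so truncated files fail loudly rather than
# being silently mis-parsed
check_fastq_shape <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0)
    abort(sprintf(
      "malformed FASTQ '%s': %d lines is not a multiple of 4 (truncated record near line %d)",
      path, length(lines), 4 * (length(lines) %/% 4) + 1))
  heads <- lines[seq(1, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad))
    abort(sprintf("malformed FASTQ '%s': record %d does not start with '@' (line %d)",
                  path, bad[1], (bad[1] - 1) * 4 + 1))
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' @param x a named character vector, or a data frame with `id`/`sequence`
#'   columns.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
  if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  out <- character(0)
  if (length(x)) {
    wrapped <- lapply(x, function(s) {
      if (nchar(s) == 0) return("")
      substring(s, seq(1, nchar(s), by = width),
                pmin(nchar(s), seq(width, nchar(s) + width - 1, by = width)))
    })
    out <- unlist(lapply(seq_along(x), function(i) {
      c(paste0(">", names(x)[i]), wrapped[[i]])
    }), use.names = FALSE)
  }
  writeLines(out, path)
  invisible(path)
}

#' Write reads to FASTQ (constant placeholder qualities)
#'
#' @param x named character vector or `id`/`sequence` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
  if (is.null(names(x))) names(x) <- paste0("read_", seq_along(x))
  qual <- vapply(x, function(s) strrep("I", nchar(s)), character(1))
  writeLines(as.vector(rbind(paste0("@", names(x)), x, "+", qual)), path)
  invisible(path)
}
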