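#' NG50-style assembly statistic
#'
#' Orders the sequence lengths from largest to smallest and accumulates
#' until the running total strictly exceeds `x`% of the reference genome
#' size; the length at which that happens is the NGx. If the total assembly
#' never exceeds the target, `NA` is returned. Note the strict inequality:
#' N50 conventions differ between implementations, and this one follows the
#' "summed length exceeds" definition.
#'
#' @param lengths sequence lengths in bases.
#' @param genome_size reference genome size in bases (> 0).
#' @param x percentage in (0, 100), e.g. 50 or 80.
#' @return a single length in bases, or `NA` if unattained.
#' @examples
#' ngx(c(10, 8, 5, 3), 20, 50)  # 8
#' @export
ngx <- function(lengths, genome_size, x) {
  if (!is.numeric(genome_size) || genome_size <= 0)
    abort("`genome_size` must be positive")
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 100)
    abort("`x` must lie strictly between 0 and 100")
  if (length(lengths) == 0) return(NA_real_)
  ls <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(ls)
  hit <- which(cum > x / 100 * genome_size)
  if (length(hit) == 0) return(NA_real_)
  ls[hit[1]]
}

#' Split scaffolds into their constituent contigs at N-gaps
#'
#' Maximal N-free runs of each scaffold are returned as contigs. On this
#' package's own scaffolds this is the exact inverse of [order_and_emit()].
#'
#' @param x scaffold sequences: tibble with a `sequence` column or a
#'   character vector.
#' @return tibble with `scaffold` (index of origin), `piece` and
#'   `sequence`.
#' @export
split_scaffolds <- function(x) {
  if (is.data.frame(x)) x <- x$sequence
  x <- as.character(x)
  parts <- strsplit(x, "N+")
  bind_rows(lapply(seq_along(parts), function(i) {
    p <- parts[[i]][nzchar(parts[[i]])]
    if (!length(p)) return(tibble(scaffold = integer(0), piece = integer(0),
                                  sequence = character(0)))
    tibble(scaffold = i, piece = seq_along(p), sequence = p)
  }))
}

#' Assembly summary statistics
#'
#' Sequences shorter than `min_len` (default 100 bases) are excluded before
#' any statistic is computed, matching the reporting convention for
#' desk-scale assemblies. Scaffold lengths include their intra-scaffold
#' gaps; pass contig lengths to summarize contigs.
#'
#' @param x sequence lengths, or a tibble with a `length` or `sequence`
#'   column.
#' @param genome_size reference genome size for NG50/NG80.
#' @param min_len reporting filter in bases.
#' @return one-row tibble: `n_sequences`, `total`, `ng50`, `ng80`, `max`,
#'   `mean`, `median`.
#' @export
assembly_summary <- function(x, genome_size, min_len = 100) {
  if (is.data.frame(x)) {
    lengths <- if ("length" %in% names(x)) x$length else nchar(x$sequence)
  } else if (is.character(x)) {
    lengths <- nchar(x)
  } else {
    lengths <- as.numeric(x)
  }
  lengths <- lengths[lengths >= min_len]
  if (length(lengths) == 0)
    return(tibble(n_sequences = 0L, total = 0, ng50 = NA_real_,
                  ng80 = NA_real_, max = NA_real_, mean = NA_real_,
                  median = NA_real_))
  tibble(n_sequences = length(lengths), total = sum(lengths),
         ng50 = ngx(lengths, genome_size, 50),
         ng80 = ngx(lengths, genome_size, 80),
         max = max(lengths), mean = mean(lengths), median = median(lengths))
}

#' Plot a k-mer multiplicity spectrum
#'
#' The bimodal shape (error mode near 1, coverage mode near the k-mer
#' depth) is what the automatic multiplicity threshold [estimate_m()]
#' exploits; the fitted threshold is drawn as a vertical line.
#'
#' @param object a `kmer_store`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot kmer_store
#' @export
autoplot.kmer_store <- function(object, ...) {
  h <- kmer_histogram(object)
  m <- tryCatch(estimate_m(h), error = function(e) NA_integer_)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$multiplicity,
                                       y = .data$count)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "k-mer multiplicity", y = "distinct k-mers",
                  title = sprintf("k-mer spectrum (k = %d)", object$k))
  if (!is.na(m))
    p <- p + ggplot2::geom_vline(xintercept = m, linetype = "dashed")
  p
}
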