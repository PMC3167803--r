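#' Configuration for the paired-read simulator
#'
#' Defaults mirror the short-insert Illumina regime the assembler targets:
#' 36 bp reads from ~200 bp insert libraries (standard deviation 20 bp),
#' uniform fragment starts, inward-facing mates, i.i.d. per-base
#' substitution errors, and optionally two haplotypes differing at planted
#' heterozygous SNP sites (each fragment drawn from either haplotype with
#' equal probability, which is what creates bubbles in the graph).
#'
#' @param genome_length genome size in bases.
#' @param read_length read length in bases (default 36).
#' @param insert_mean,insert_sd insert size model (outer end to outer end),
#'   normal with rounding, clamped to `[2 * read_length, genome_length]`.
#' @param coverage target base coverage; the pair count is
#'   `round(coverage * genome_length / (2 * read_length))`.
#' @param error_rate per-base substitution probability.
#' @param het_snp_rate per-base heterozygous SNP probability.
#' @param seed random seed; all outputs are bit-reproducible given the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 20000, read_length = 36,
                       insert_mean = 200, insert_sd = 20, coverage = 30,
                       error_rate = 0, het_snp_rate = 0, seed = 1L) {
  stopifnot(genome_length >= 10 * read_length,
            error_rate >= 0, error_rate <= 1,
            het_snp_rate >= 0, het_snp_rate <= 1,
            coverage > 0,
            insert_mean + 3 * insert_sd < genome_length)
  structure(list(genome_length = as.integer(genome_length),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, error_rate = error_rate,
                 het_snp_rate = het_snp_rate, seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate a random genome
#'
#' Uniform random A/C/G/T sequence. With `repeat_free_k` set, the genome is
#' rejection-resampled until it contains no exact repeat of length
#' `repeat_free_k - 1` on either strand, the condition under which the
#' de Bruijn graph at that k is a single branch-free path and assembly must
#' reconstruct the genome exactly. Feasible for desk-scale genomes
#' (<= 100 kb).
#'
#' @param cfg a [sim_config()].
#' @param repeat_free_k optional k; enforce no repeated `(k-1)`-mer.
#' @param max_tries resampling attempts before giving up.
#' @return a single character string; attribute `"seed"` records the seed.
#' @export
simulate_genome <- function(cfg, repeat_free_k = NULL, max_tries = 50) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  for (i in seq_len(max_tries)) {
    g <- paste(sample(BASES, cfg$genome_length, replace = TRUE), collapse = "")
    if (is.null(repeat_free_k) || is_repeat_free(g, repeat_free_k))
      return(structure(g, seed = cfg$seed))
  }
  abort(sprintf(
    "no repeat-free genome of length %d found in %d tries at k = %d; try a larger k",
    cfg$genome_length, max_tries, repeat_free_k))
}

# no (k-1)-mer occurs twice across the genome and its reverse complement
is_repeat_free <- function(genome, k) {
  w <- k - 1
  n <- nchar(genome)
  if (n < w) return(TRUE)
  fw <- substring(genome, 1:(n - w + 1), w:n)
  rv <- substring(rc_chr(genome), 1:(n - w + 1), w:n)
  anyDuplicated(c(fw, rv)) == 0
}

#' Simulate paired-end reads from a genome
#'
#' Fragment starts are uniform; the insert length is
#' `round(rnorm(insert_mean, insert_sd))` clamped to
#' `[2 * read_length, genome_length]`; mate 1 is the first `read_length`
#' bases of the fragment on the forward strand, mate 2 the reverse
#' complement of the last `read_length` bases, so the mates face inward.
#' With `het_snp_rate > 0` (or explicit `snp_positions`) an alternative
#' haplotype is created by substituting the planted sites, and each fragment
#' is drawn from either haplotype with probability 1/2. Substitution errors
#' are applied i.i.d. per base after fragment extraction.
#'
#' @param genome genome string from [simulate_genome()].
#' @param cfg a [sim_config()].
#' @param snp_positions optional explicit 1-based heterozygous sites
#'   (overrides `het_snp_rate`).
#' @return list with `pairs` (tibble `id`, `read_1`, `read_2`), `truth`
#'   (tibble of fragment coordinates, insert sizes, haplotype of origin)
#'   and `snps` (tibble `pos`, `ref`, `alt`).
#' @export
simulate_pairs <- function(genome, cfg, snp_positions = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- as.character(genome)[1]
  L <- nchar(genome)
  rl <- cfg$read_length
  set.seed(cfg$seed + 1L)

  if (is.null(snp_positions) && cfg$het_snp_rate > 0)
    snp_positions <- which(runif(L) < cfg$het_snp_rate)
  snps <- tibble(pos = integer(0), ref = character(0), alt = character(0))
  hap2 <- genome
  if (length(snp_positions)) {
    ref <- substring(genome, snp_positions, snp_positions)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1),
                  USE.NAMES = FALSE)
    snps <- tibble(pos = as.integer(snp_positions), ref = ref, alt = alt)
    h2 <- strsplit(genome, "")[[1]]
    h2[snp_positions] <- alt
    hap2 <- paste(h2, collapse = "")
  }

  n_pairs <- max(1L, as.integer(round(cfg$coverage * L / (2 * rl))))
  ins <- pmin(pmax(round(rnorm(n_pairs, cfg$insert_mean, cfg$insert_sd)),
                   2L * rl), L)
  # fragments may overhang the molecule ends by up to one read length and
  # are truncated there, so terminal bases are sampled at the same depth as
  # interior ones (fragmentation of a linear molecule produces fragments
  # abutting the ends; a hard in-range start would leave the first and last
  # read-length of the genome essentially uncovered)
  over <- pmin(rl, pmax(0L, ins - 2L * rl))
  raw <- floor(runif(n_pairs) * (L - ins + 1 + 2 * over)) + 1L - over
  start <- pmax(1L, raw)
  fend <- pmin(L, raw + ins - 1L)
  ins <- fend - start + 1L
  hap <- if (length(snp_positions)) sample(1:2, n_pairs, replace = TRUE)
         else rep(1L, n_pairs)

  src <- ifelse(hap == 1L, genome, hap2)
  r1 <- substring(src, start, start + rl - 1L)
  r2 <- rc_chr(substring(src, fend - rl + 1L, fend))
  if (cfg$error_rate > 0) {
    r1 <- add_errors(r1, cfg$error_rate)
    r2 <- add_errors(r2, cfg$error_rate)
  }
  list(pairs = tibble(id = sprintf("pair_%06d", seq_len(n_pairs)),
                      read_1 = r1, read_2 = r2),
       truth = tibble(pair = seq_len(n_pairs), start = as.integer(start),
                      insert = as.integer(ins), haplotype = as.integer(hap)),
       snps = snps)
}

# i.i.d. substitutions; a hit base becomes one of the three other bases
add_errors <- function(reads, rate) {
  nerr <- rbinom(length(reads), nchar(reads), rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    s <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(s), nerr[i])
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(BASES, b), 1),
                     character(1), USE.NAMES = FALSE)
    reads[i] <- paste(s, collapse = "")
  }
  reads
}
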