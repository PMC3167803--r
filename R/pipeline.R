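#' Assemble reads in memory
#'
#' Runs the whole pipeline on in-memory reads: canonical k-mer counting,
#' linkage construction, low-frequency dead-end removal under the
#' automatically estimated threshold, tip clipping, unitig extraction,
#' read threading into the sequence graph, bubble merging, and contig
#' emission. With `pairs_1`/`pairs_2` supplied, paired-end scaffolding runs
#' as well.
#'
#' @param reads reads used for contig assembly (character vector or data
#'   frame). For paired data pass the concatenation of both mate files.
#' @param k k-mer length (odd, <= 31); the one mandatory parameter.
#' @param n_parts number of k-mer partitions.
#' @param r acceleration-table prefix bits.
#' @param m multiplicity threshold; `NULL` to estimate from the spectrum.
#' @param min_coverage minimum unitig chain coverage.
#' @param min_pairs minimum supporting pairs for a scaffold link.
#' @param min_len minimum reported contig/scaffold length.
#' @param pairs_1,pairs_2 optional mate reads for scaffolding.
#' @param min_insert_pairs same-contig pairs required for insert estimation.
#' @return list with `unitigs`, `contigs`, and when pairs are given
#'   `pair_db`, `insert_stats`, `links`, `scaffolds`; plus a `log` tibble of
#'   per-stage counts.
#' @export
assemble <- function(reads, k, n_parts = 1, r = 24, m = NULL,
                     min_coverage = 1, min_pairs = 3, min_len = 100,
                     pairs_1 = NULL, pairs_2 = NULL, min_insert_pairs = 100) {
  k <- check_k(k)
  reads <- sanitize_read(as_read_vector(reads))
  st <- count_kmers(reads, k, n_parts = n_parts, r = r)
  n_kmers <- store_size(st)
  add_read_linkages(st, reads)
  st <- remove_low_frequency_dead_ends(st, m)
  m_used <- attr(st, "m")
  n_lowfreq <- attr(st, "removed")
  st <- remove_tips(st)
  n_tips <- attr(st, "tips_removed")
  compact_store(st)
  unitigs <- extract_chains(st, min_coverage = min_coverage)

  g <- build_sequence_graph(unitigs, reads, k)
  g <- merge_bubbles(g)
  n_bubbles <- attr(g, "merged")
  contigs <- finalize_contigs(g, min_len = min_len)

  log <- tibble(stage = c("kmers", "simplify", "unitigs", "contigs"),
                detail = c(sprintf("k=%d n_parts=%d n_kmers=%d", k, n_parts,
                                   as.integer(n_kmers)),
                           sprintf("M=%d low_freq_removed=%d tips_removed=%d",
                                   m_used, n_lowfreq, n_tips),
                           sprintf("n_unitigs=%d kept=%d", nrow(unitigs),
                                   sum(unitigs$kept)),
                           sprintf("n_contigs=%d merged_bubbles=%d",
                                   nrow(contigs), n_bubbles)))
  out <- list(unitigs = unitigs, contigs = contigs, log = log)

  if (!is.null(pairs_1)) {
    stopifnot(!is.null(pairs_2))
    db <- map_pairs(contigs, pairs_1, pairs_2, k)
    stats <- estimate_insert_stats(db, min_pairs = min_insert_pairs)
    links <- build_links(db, stats, min_pairs = min_pairs)
    scaffolds <- order_and_emit(links, contigs, min_len = min_len)
    out$pair_db <- db
    out$insert_stats <- stats
    out$links <- links
    out$scaffolds <- scaffolds
    out$log <- bind_rows(out$log, tibble(
      stage = "scaffold",
      detail = sprintf("mapped_pairs=%d links=%d scaffolds=%d", nrow(db),
                       nrow(links), nrow(scaffolds))))
  }
  out
}

#' Pipeline configuration
#'
#' Collects the staged pipeline's parameters and file paths. Only `k` is
#' mandatory; everything else has a documented default. Even `k` is
#' rejected at configuration time: palindromic k-mers would make canonical
#' strands ambiguous.
#'
#' @param k k-mer length (odd, in 1..31).
#' @param reads input read files (FASTA/FASTQ, optionally gzipped).
#' @param out_dir directory for stage artifacts.
#' @param pairs_1,pairs_2 optional paired read files for scaffolding.
#' @param n_parts,r,m,min_coverage,min_pairs,min_len,min_insert_pairs see
#'   [assemble()].
#' @param seed seed recorded for provenance.
#' @return an `assembly_config` list.
#' @export
assembly_config <- function(k, reads = character(0), out_dir = tempfile("asm_"),
                            pairs_1 = NULL, pairs_2 = NULL, n_parts = 1,
                            r = 24, m = NULL, min_coverage = 1, min_pairs = 3,
                            min_len = 100, min_insert_pairs = 100, seed = 1L) {
  structure(list(k = check_k(k), reads = reads, out_dir = out_dir,
                 pairs_1 = pairs_1, pairs_2 = pairs_2,
                 n_parts = as.integer(n_parts), r = as.integer(r), m = m,
                 min_coverage = min_coverage, min_pairs = min_pairs,
                 min_len = min_len, min_insert_pairs = min_insert_pairs,
                 seed = as.integer(seed)),
            class = "assembly_config")
}

read_any <- function(path) {
  con <- gzfile(path, "r")
  first <- substr(readLines(con, n = 1), 1, 1)
  close(con)
  if (identical(first, "@")) read_fastq(path) else read_fasta(path)
}

load_config_reads <- function(cfg) {
  if (!length(cfg$reads)) abort("no input read files configured")
  missing <- cfg$reads[!file.exists(cfg$reads)]
  if (length(missing)) abort(paste0("input file not found: ", missing[1]))
  unlist(lapply(cfg$reads, function(p) read_any(p)$sequence))
}

stage_file <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(path, stage, produced_by) {
  ok <- length(path) > 0 && !anyNA(path) && all(file.exists(path))
  if (!ok) {
    what <- if (length(path) == 0 || anyNA(path)) "its input artifact"
            else paste0("'", path[!file.exists(path)][1], "'")
    abort(sprintf("stage '%s' requires %s; run stage '%s' first",
                  stage, what, produced_by))
  }
}

#' Run the staged assembly pipeline
#'
#' Four stages, runnable individually or end to end, each consuming the
#' previous stage's on-disk artifacts in `cfg$out_dir`:
#' \describe{
#'   \item{kmers}{count canonical k-mers, write one `.pshk` partition file
#'     per partition}
#'   \item{graph}{reload the k-mer files, build linkages, simplify, write
#'     `unitigs.fasta`}
#'   \item{contigs}{thread reads over unitigs, merge bubbles, write
#'     `contigs.fasta`}
#'   \item{scaffold}{map pairs, estimate inserts, write `links.tsv` and
#'     `scaffolds.fasta`}
#' }
#' Per-stage summary lines go to standard error via `message()`.
#'
#' @param cfg an [assembly_config()].
#' @param stages which stages to run, in pipeline order.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(cfg, stages = c("kmers", "graph", "contigs",
                                         "scaffold")) {
  stopifnot(inherits(cfg, "assembly_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  arts <- list(kmers = Sys.glob(stage_file(cfg, "kmers_p*.pshk")),
               unitigs = stage_file(cfg, "unitigs.fasta"),
               contigs = stage_file(cfg, "contigs.fasta"),
               links = stage_file(cfg, "links.tsv"),
               scaffolds = stage_file(cfg, "scaffolds.fasta"))

  if ("kmers" %in% stages) {
    reads <- load_config_reads(cfg)
    st <- count_kmers(reads, cfg$k, n_parts = cfg$n_parts, r = cfg$r)
    arts$kmers <- write_kmer_files(st, cfg$out_dir)
    message(sprintf("stage=kmers k=%d n_parts=%d n_kmers=%d files=%d",
                    cfg$k, cfg$n_parts, as.integer(store_size(st)),
                    length(arts$kmers)))
  }
  if ("graph" %in% stages) {
    require_artifact(arts$kmers, "graph", "kmers")
    st <- store_from_kmer_files(arts$kmers, n_parts = cfg$n_parts, r = cfg$r)
    if (st$k != cfg$k)
      abort(sprintf("k-mer files were built at k=%d but the config says k=%d",
                    st$k, cfg$k))
    reads <- load_config_reads(cfg)
    add_read_linkages(st, reads)
    st <- remove_low_frequency_dead_ends(st, cfg$m)
    nlow <- attr(st, "removed"); mu <- attr(st, "m")
    st <- remove_tips(st)
    ntip <- attr(st, "tips_removed")
    compact_store(st)
    unitigs <- extract_chains(st, min_coverage = cfg$min_coverage)
    write_unitigs(unitigs, arts$unitigs)
    message(sprintf(
      "stage=graph M=%d low_freq_removed=%d tips_removed=%d unitigs=%d kept=%d",
      mu, nlow, ntip, nrow(unitigs), sum(unitigs$kept)))
  }
  if ("contigs" %in% stages) {
    require_artifact(arts$unitigs, "contigs", "graph")
    unitigs <- read_fasta(arts$unitigs)
    # headers carry the per-base chain coverage; convert to mean k-mer
    # multiplicity for the node-level filters
    chain_cov <- suppressWarnings(
      as.numeric(sub(".*cov=([0-9.]+).*", "\\1", unitigs$id)))
    len <- nchar(unitigs$sequence)
    node_cov <- ifelse(is.na(chain_cov), 1,
                       chain_cov * len / pmax(1, len - cfg$k + 1))
    reads <- load_config_reads(cfg)
    g <- build_sequence_graph(
      tibble(sequence = unitigs$sequence, coverage = node_cov), reads, cfg$k)
    g <- merge_bubbles(g)
    contigs <- finalize_contigs(g, min_len = cfg$min_len)
    write_contigs(contigs, arts$contigs)
    message(sprintf("stage=contigs contigs=%d merged_bubbles=%d",
                    nrow(contigs), attr(g, "merged")))
  }
  if ("scaffold" %in% stages) {
    require_artifact(arts$contigs, "scaffold", "contigs")
    if (is.null(cfg$pairs_1) || is.null(cfg$pairs_2)) {
      message("stage=scaffold skipped=no_paired_input")
    } else {
      contigs <- read_fasta(arts$contigs) %>%
        mutate(contig = row_number(), length = nchar(.data$sequence))
      p1 <- read_any(cfg$pairs_1)$sequence
      p2 <- read_any(cfg$pairs_2)$sequence
      db <- map_pairs(contigs, p1, p2, cfg$k)
      stats <- estimate_insert_stats(db, min_pairs = cfg$min_insert_pairs)
      links <- build_links(db, stats, min_pairs = cfg$min_pairs)
      scaffolds <- order_and_emit(links, contigs, min_len = cfg$min_len)
      write_links(links, arts$links)
      write_scaffolds(scaffolds, arts$scaffolds)
      message(sprintf(
        "stage=scaffold mapped_pairs=%d links=%d scaffolds=%d",
        nrow(db), nrow(links), nrow(scaffolds)))
    }
  }
  invisible(arts)
}
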