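#' Map read pairs onto contigs
#'
#' Each mate is aligned k-mer by k-mer against the contig set: it maps to a
#' contig when at least `min_frac` (default 80%) of its k-mers hit that
#' contig on one consistent diagonal (consecutive offsets). Mates with tied
#' placements on two contigs are ambiguous and dropped; a pair is recorded
#' only when both mates map. Offsets are 0-based leftmost coordinates.
#'
#' @param contigs tibble from [finalize_contigs()] (or any `sequence`
#'   tibble / character vector).
#' @param reads_1,reads_2 mate files' sequences (character vectors or
#'   data frames), in matching order.
#' @param k k-mer length used for alignment.
#' @param min_frac minimum fraction of a mate's k-mers supporting the
#'   placement.
#' @param library_id library label for insert-size estimation.
#' @return tibble with one row per fully mapped pair: `pair`, `library`,
#'   `contig_1`, `strand_1`, `start_1`, `len_1`, and the `_2` counterparts.
#'   Contig lengths are carried in attribute `"contig_lengths"`.
#' @export
map_pairs <- function(contigs, reads_1, reads_2, k, min_frac = 0.8,
                      library_id = "lib1") {
  k <- check_k(k)
  if (is.character(contigs)) contigs <- tibble(sequence = contigs)
  seqs <- contigs$sequence
  r1 <- sanitize_read(as_read_vector(reads_1))
  r2 <- sanitize_read(as_read_vector(reads_2))
  if (length(r1) != length(r2))
    abort(sprintf("unpaired input: %d mate-1 reads but %d mate-2 reads",
                  length(r1), length(r2)))
  mp <- cpp_build_node_map(seqs, k)
  m1 <- cpp_map_reads(mp, r1, min_frac)
  m2 <- cpp_map_reads(mp, r2, min_frac)
  db <- tibble(pair = seq_along(r1), library = library_id,
               contig_1 = m1$node, strand_1 = m1$strand, start_1 = m1$start,
               len_1 = nchar(r1),
               contig_2 = m2$node, strand_2 = m2$strand, start_2 = m2$start,
               len_2 = nchar(r2)) %>%
    filter(!is.na(.data$contig_1), !is.na(.data$contig_2))
  attr(db, "contig_lengths") <- nchar(seqs)
  db
}

#' Estimate per-library insert statistics
#'
#' Uses only pairs whose two mates map onto the same contig, where the
#' insert is observed directly: the span from the leftmost mapped base to
#' the rightmost (outer end to outer end). Reports the median and standard
#' deviation per library.
#'
#' @param db pair database from [map_pairs()].
#' @param min_pairs minimum number of same-contig pairs required (default
#'   100); fewer is an estimation error naming the library.
#' @return tibble with `library`, `n_pairs`, `median_insert`, `insert_sd`.
#' @export
estimate_insert_stats <- function(db, min_pairs = 100) {
  same <- db %>% filter(.data$contig_1 == .data$contig_2)
  if (nrow(same) == 0) abort("no same-contig pairs to estimate insert sizes from")
  out <- same %>%
    mutate(span = pmax(.data$start_1 + .data$len_1,
                       .data$start_2 + .data$len_2) -
             pmin(.data$start_1, .data$start_2)) %>%
    group_by(.data$library) %>%
    summarise(n_pairs = n(), median_insert = median(.data$span),
              insert_sd = sd(.data$span), .groups = "drop")
  short <- out$library[out$n_pairs < min_pairs]
  if (length(short))
    abort(sprintf(
      "library '%s' has only %d same-contig pairs (%d required) for insert estimation",
      short[1], out$n_pairs[out$library == short[1]][1], min_pairs))
  out
}

#' Build scaffold links from cross-contig pairs
#'
#' Cross-contig pair mappings are grouped by the pair of contig ends they
#' connect (a mate on the forward strand points out of its contig's right
#' end, a reverse mate out of the left end). Each supporting pair
#' contributes a gap observation `median_insert - tail_1 - tail_2`, where a
#' tail is the distance from the mate's outer end to the contig end in the
#' implied direction. Only groups with at least `min_pairs` supporting
#' pairs (default 3) become reliable links; single-read multi-contig
#' evidence is never used. Pairs implying contradictory orientations fall
#' into different groups by construction.
#'
#' @param db pair database from [map_pairs()].
#' @param stats insert statistics from [estimate_insert_stats()].
#' @param min_pairs minimum supporting pairs for a reliable link.
#' @return tibble with `contig_a`, `side_a`, `contig_b`, `side_b`,
#'   `orientation` (FF/FR/RF/RR), `n_pairs`, `gap_estimate`, `gap_sd`.
#' @export
build_links <- function(db, stats, min_pairs = 3) {
  clen <- attr(db, "contig_lengths")
  cross <- db %>% filter(.data$contig_1 != .data$contig_2) %>%
    left_join(stats %>% select("library", "median_insert", "insert_sd"),
              by = "library")
  if (nrow(cross) == 0)
    return(tibble(contig_a = integer(0), side_a = character(0),
                  contig_b = integer(0), side_b = character(0),
                  orientation = character(0), n_pairs = integer(0),
                  gap_estimate = numeric(0), gap_sd = numeric(0)))
  side_1 <- ifelse(cross$strand_1 > 0, "R", "L")
  side_2 <- ifelse(cross$strand_2 > 0, "R", "L")
  tail_1 <- ifelse(cross$strand_1 > 0,
                   clen[cross$contig_1] - cross$start_1,
                   cross$start_1 + cross$len_1)
  tail_2 <- ifelse(cross$strand_2 > 0,
                   clen[cross$contig_2] - cross$start_2,
                   cross$start_2 + cross$len_2)
  gap <- cross$median_insert - tail_1 - tail_2
  swap <- cross$contig_1 > cross$contig_2
  obs <- tibble(
    contig_a = ifelse(swap, cross$contig_2, cross$contig_1),
    side_a = ifelse(swap, side_2, side_1),
    contig_b = ifelse(swap, cross$contig_1, cross$contig_2),
    side_b = ifelse(swap, side_1, side_2),
    gap = gap, insert_sd = cross$insert_sd)
  obs %>%
    group_by(.data$contig_a, .data$side_a, .data$contig_b, .data$side_b) %>%
    summarise(n_pairs = n(), gap_estimate = mean(.data$gap),
              gap_sd = ifelse(n() > 1, sd(.data$gap), .data$insert_sd[1]),
              .groups = "drop") %>%
    filter(.data$n_pairs >= min_pairs) %>%
    mutate(orientation = paste0(ifelse(.data$side_a == "R", "F", "R"),
                                ifelse(.data$side_b == "L", "F", "R"))) %>%
    select("contig_a", "side_a", "contig_b", "side_b", "orientation",
           "n_pairs", "gap_estimate", "gap_sd") %>%
    arrange(desc(.data$n_pairs), .data$contig_a, .data$contig_b)
}

#' Order and orient contigs into N-gapped scaffolds
#'
#' Greedy path construction: links are visited by descending supporting
#' pair count; a link is accepted when both contig ends are still free and
#' joining them does not close a cycle (the lowest-support link of a cycle
#' is rejected and logged). Accepted links form simple paths; each path is
#' emitted as one scaffold with gaps rendered as runs of `N` of length
#' `max(1, round(gap_estimate))` (negative gap estimates, slightly
#' overlapping contigs, clamp to a single `N` rather than attempting an
#' overlap merge). Unlinked contigs are emitted as singleton scaffolds.
#' Every contig appears in exactly one scaffold, once, in one orientation;
#' splitting the output at N-runs recovers the input contigs exactly.
#'
#' @param links tibble from [build_links()].
#' @param contigs contig tibble (`sequence` column) the links refer to.
#' @param min_len minimum scaffold length to report (default 100).
#' @return tibble with `scaffold`, `sequence`, `length`, `n_contigs`;
#'   attribute `"layout"` details contig order, orientation and rendered
#'   gaps; attribute `"rejected"` lists cycle-rejected links.
#' @export
order_and_emit <- function(links, contigs, min_len = 100) {
  if (is.character(contigs)) contigs <- tibble(sequence = contigs)
  nc <- nrow(contigs)
  seqs <- contigs$sequence
  # union-find for cycle avoidance
  parent <- seq_len(nc)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  end_link <- list()  # "contig.side" -> list(other contig, other side, gap)
  rejected <- links[0, , drop = FALSE]
  if (nrow(links)) {
    links <- links %>% arrange(desc(.data$n_pairs), .data$contig_a,
                               .data$contig_b, .data$side_a, .data$side_b)
    for (i in seq_len(nrow(links))) {
      la <- links[i, ]
      ka <- paste0(la$contig_a, ".", la$side_a)
      kb <- paste0(la$contig_b, ".", la$side_b)
      if (!is.null(end_link[[ka]]) || !is.null(end_link[[kb]])) next
      ra <- find(la$contig_a); rb <- find(la$contig_b)
      if (ra == rb) { rejected <- bind_rows(rejected, la); next }
      parent[ra] <- rb
      end_link[[ka]] <- list(contig = la$contig_b, side = la$side_b,
                             gap = la$gap_estimate)
      end_link[[kb]] <- list(contig = la$contig_a, side = la$side_a,
                             gap = la$gap_estimate)
    }
  }
  linked_sides <- names(end_link)
  # walk each path from a terminal contig
  emitted <- rep(FALSE, nc)
  scaffolds <- list()
  for (c0 in seq_len(nc)) {
    if (emitted[c0]) next
    free_r <- !(paste0(c0, ".R") %in% linked_sides)
    free_l <- !(paste0(c0, ".L") %in% linked_sides)
    if (!free_l && !free_r) next  # interior contig; reached from a terminal
    # orient so that we exit through the linked side (forward if exiting R)
    exit_side <- if (free_l && !free_r) "R" else if (free_r && !free_l) "L"
                 else "R"  # singleton: arbitrary forward
    cur <- c0
    ori <- if (exit_side == "R") "F" else "R"
    layout <- tibble(contig = cur, orientation = ori, gap_after = NA_real_)
    emitted[cur] <- TRUE
    repeat {
      lk <- end_link[[paste0(cur, ".", exit_side)]]
      if (is.null(lk)) break
      layout$gap_after[nrow(layout)] <- lk$gap
      cur <- lk$contig
      entry <- lk$side
      ori <- if (entry == "L") "F" else "R"
      exit_side <- if (entry == "L") "R" else "L"
      layout <- bind_rows(layout,
                          tibble(contig = cur, orientation = ori,
                                 gap_after = NA_real_))
      emitted[cur] <- TRUE
    }
    scaffolds[[length(scaffolds) + 1]] <- layout
  }
  seq_of <- function(layout) {
    pieces <- character(0)
    for (i in seq_len(nrow(layout))) {
      s <- seqs[layout$contig[i]]
      if (layout$orientation[i] == "R") s <- rc_chr(s)
      pieces <- c(pieces, s)
      if (!is.na(layout$gap_after[i]))
        pieces <- c(pieces, strrep("N", max(1, round(layout$gap_after[i]))))
    }
    paste(pieces, collapse = "")
  }
  out <- tibble(sequence = vapply(scaffolds, seq_of, character(1)),
                n_contigs = vapply(scaffolds, nrow, integer(1)))
  keep <- nchar(out$sequence) >= min_len
  out <- out[keep, , drop = FALSE]
  scaffolds <- scaffolds[keep]
  o <- order(out$sequence)
  out <- out[o, , drop = FALSE]
  scaffolds <- scaffolds[o]
  out <- out %>%
    mutate(scaffold = row_number(), length = nchar(.data$sequence)) %>%
    select("scaffold", "sequence", "length", "n_contigs")
  layout <- bind_rows(lapply(seq_along(scaffolds), function(i) {
    scaffolds[[i]] %>% mutate(scaffold = i, position = row_number()) %>%
      select("scaffold", "position", "contig", "orientation", "gap_after")
  }))
  attr(out, "layout") <- layout
  attr(out, "rejected") <- rejected
  out
}

#' Write scaffolds to FASTA and the link report to TSV
#' @param scaffolds tibble from [order_and_emit()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_scaffolds <- function(scaffolds, path) {
  ids <- sprintf("scaffold_%d len=%d contigs=%d", scaffolds$scaffold,
                 scaffolds$length, scaffolds$n_contigs)
  write_fasta(setNames(scaffolds$sequence, ids), path)
}

#' @rdname write_scaffolds
#' @param links tibble from [build_links()].
#' @export
write_links <- function(links, path) {
  write.table(links, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
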