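#' Construct a twin-node sequence graph
#'
#' Nodes are sequences (unitigs or contigs); every node implicitly carries a
#' twin representing its reverse complement, addressed by a negative id.
#' Edges are stored once in a twin-normalized form: the directed edge
#' `u -> v` and its mirror `-v -> -u` are the same edge.
#'
#' @param nodes tibble with columns `sequence` and optionally `coverage`
#'   (default 1); or a character vector of sequences.
#' @param edges tibble with columns `from`, `to` (signed 1-based node ids)
#'   and `support`; may be empty.
#' @param k the k-mer length the sequences were assembled at (adjacent nodes
#'   overlap by `k - 1` bases).
#' @return a `seq_graph` object.
#' @export
seq_graph <- function(nodes, edges = NULL, k) {
  k <- check_k(k)
  if (is.character(nodes)) nodes <- tibble(sequence = nodes)
  nodes <- as_tibble(nodes)
  if (!"coverage" %in% names(nodes)) nodes$coverage <- 1
  nodes <- tibble(node = seq_len(nrow(nodes)),
                  sequence = toupper(nodes$sequence),
                  length = nchar(nodes$sequence),
                  coverage = as.numeric(nodes$coverage))
  if (any(nodes$length < k)) abort("every node sequence must have length >= k")
  if (is.null(edges)) edges <- tibble(from = integer(0), to = integer(0),
                                      support = integer(0))
  edges <- as_tibble(edges)
  if (!"support" %in% names(edges)) edges$support <- 1L
  edges <- normalize_edges(edges)
  structure(list(nodes = nodes, edges = edges, k = k), class = "seq_graph")
}

normalize_edges <- function(edges) {
  if (nrow(edges) == 0)
    return(tibble(from = integer(0), to = integer(0), support = integer(0)))
  swap <- (-edges$to < edges$from) |
    (-edges$to == edges$from & -edges$from < edges$to)
  f <- ifelse(swap, -edges$to, edges$from)
  t <- ifelse(swap, -edges$from, edges$to)
  tibble(from = as.integer(f), to = as.integer(t),
         support = as.integer(edges$support)) %>%
    group_by(.data$from, .data$to) %>%
    summarise(support = sum(.data$support), .groups = "drop") %>%
    arrange(.data$from, .data$to)
}

# both directions of every edge (u -> v and -v -> -u), deduplicated
directed_edges <- function(g) {
  e <- g$edges
  bind_rows(e, tibble(from = -e$to, to = -e$from, support = e$support)) %>%
    distinct(.data$from, .data$to, .keep_all = TRUE)
}

node_seq <- function(g, u) {
  s <- g$nodes$sequence[abs(u)]
  if (u < 0) rc_chr(s) else s
}

# bases a node contributes when appended after another node (k-1 overlap)
node_contrib <- function(g, u) substring(node_seq(g, u), g$k)

#' @export
print.seq_graph <- function(x, ...) {
  cat(sprintf("<seq_graph> k = %d, %d node(s) + twins, %d edge(s)\n",
              x$k, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @method tidy seq_graph
#' @export
tidy.seq_graph <- function(x, ...) x$nodes

#' @method glance seq_graph
#' @export
glance.seq_graph <- function(x, ...) {
  tibble(k = x$k, n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         total_bases = sum(x$nodes$length),
         median_coverage = median(x$nodes$coverage))
}

#' Build the sequence graph from unitigs by threading reads
#'
#' Every unitig becomes a node (plus twin). Reads are aligned to the nodes
#' k-mer by k-mer; whenever two adjacent k-mers of a read fall in two
#' different nodes, the corresponding oriented edge is created, or its
#' support incremented if it already exists. No per-read mapping information
#' is retained. Read k-mers absent from every node were filtered upstream
#' and are skipped silently.
#'
#' @param unitigs output of [extract_chains()] (kept rows are used), a
#'   tibble with `sequence` (and optional `coverage`) columns, or a
#'   character vector.
#' @param reads the original reads (character vector or data frame).
#' @param k k-mer length (must match the unitig stage).
#' @return a `seq_graph`.
#' @export
build_sequence_graph <- function(unitigs, reads, k) {
  k <- check_k(k)
  if (is.data.frame(unitigs) && "kept" %in% names(unitigs))
    unitigs <- unitigs[unitigs$kept, , drop = FALSE]
  if (is.data.frame(unitigs) &&
      all(c("mult_sum", "kmer_count") %in% names(unitigs))) {
    # node coverage is the mean k-mer multiplicity: unlike the per-base
    # chain coverage it does not penalize short nodes, whose k-mer count
    # is much smaller than their base length
    unitigs <- tibble(sequence = unitigs$sequence,
                      coverage = unitigs$mult_sum / unitigs$kmer_count)
  }
  g <- seq_graph(unitigs, NULL, k)
  reads <- sanitize_read(as_read_vector(reads))
  mp <- cpp_build_node_map(g$nodes$sequence, k)
  th <- cpp_thread_reads(mp, reads)
  g$edges <- normalize_edges(tibble(from = th$from, to = th$to,
                                    support = th$support))
  g
}

# shortest base-distance search from `start` (excluding the source node s),
# used by the bubble detector; returns dist/pred keyed by signed node id
shortest_paths_from <- function(dir, g, start, forbid, max_depth) {
  dist <- setNames(0, as.character(start))
  pred <- setNames(NA_integer_, as.character(start))
  queue <- start
  while (length(queue)) {
    u <- queue[[1]]; queue <- queue[-1]
    du <- dist[[as.character(u)]]
    # the bound applies to the path walked so far; the node reached may be
    # arbitrarily long (it is usually the reconvergence sink)
    if (du > max_depth) next
    outs <- dir[dir$from == u, , drop = FALSE]
    for (v in outs$to) {
      if (abs(v) %in% forbid) next
      dv <- du + g$nodes$length[abs(v)] - (g$k - 1)
      key <- as.character(v)
      if (!(key %in% names(dist)) || dv < dist[[key]]) {
        dist[key] <- dv
        pred[key] <- u
        queue <- c(queue, v)
      }
    }
  }
  list(dist = dist, pred = pred)
}

trace_path <- function(pred, t) {
  path <- t
  while (!is.na(pred[[as.character(path[1])]])) {
    path <- c(pred[[as.character(path[1])]], path)
  }
  path
}

# alignment identity: matches over alignment length (gaps included),
# global alignment with unit costs
path_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 1)
  alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  Biostrings::nmatch(pa) / alen
}

# the sequence a bubble branch spells: its interior node chain with the
# k-1 overlaps collapsed. Reverse-complement-symmetric, so both traversal
# directions of the same bubble see the same identity.
branch_sequence <- function(g, interior) {
  if (!length(interior)) return("")
  paste(c(node_seq(g, interior[1]),
          vapply(interior[-1], function(u) node_contrib(g, u),
                 character(1))), collapse = "")
}

#' Detect and merge bubbles
#'
#' Bubbles are pairs of short parallel paths sharing a source and a sink
#' node, caused by heterozygous SNPs, internal read errors or joined tips.
#' From every branching oriented node, a Tour-bus style shortest-path
#' traversal (priority = path length in bases, bounded by `max_depth`)
#' looks for a reconvergent node reachable from two different out-edges
#' with internally disjoint paths. A detected pair is merged if and only if
#' the two branch sequences (each branch's interior node chain, `k - 1`
#' overlaps collapsed) differ by at most `max_len_diff` bases in length
#' with identity at least `min_identity`: the lower-coverage branch is
#' removed and its coverage folded into the higher-coverage branch. Merging
#' repeats until no mergeable bubble remains.
#'
#' Only bubbles whose losing branch has no edges to nodes outside the
#' bubble are merged; entangled branches are left for the coverage filter.
#'
#' @param g a `seq_graph`.
#' @param max_len_diff maximum path length difference in bases (default 2).
#' @param min_identity minimum alignment identity (default 0.90).
#' @param max_depth traversal bound in bases (default `5 * k`).
#' @return the merged `seq_graph`; attribute `"merged"` counts merges.
#' @export
merge_bubbles <- function(g, max_len_diff = 2, min_identity = 0.90,
                          max_depth = NULL) {
  stopifnot(inherits(g, "seq_graph"))
  if (is.null(max_depth)) max_depth <- 5 * g$k
  n_merged <- 0L
  repeat {
    hit <- find_mergeable_bubble(g, max_len_diff, min_identity, max_depth)
    if (is.null(hit)) break
    g <- pop_bubble(g, hit)
    n_merged <- n_merged + 1L
    if (n_merged > 10000L) abort("bubble merging failed to converge")
  }
  attr(g, "merged") <- n_merged
  g
}

find_mergeable_bubble <- function(g, max_len_diff, min_identity, max_depth) {
  dir <- directed_edges(g)
  if (nrow(dir) == 0) return(NULL)
  outdeg <- table(dir$from)
  sources <- as.integer(names(outdeg)[outdeg >= 2])
  sources <- sources[order(abs(sources), sources)]
  for (s in sources) {
    nb <- sort(dir$to[dir$from == s])
    for (ai in seq_len(length(nb) - 1)) {
      for (bi in (ai + 1):length(nb)) {
        a <- nb[ai]; b <- nb[bi]
        if (abs(a) == abs(b)) next
        spa <- shortest_paths_from(dir, g, a, forbid = abs(s), max_depth)
        spb <- shortest_paths_from(dir, g, b, forbid = abs(s), max_depth)
        common <- intersect(names(spa$dist), names(spb$dist))
        if (!length(common)) next
        tot <- spa$dist[common] + spb$dist[common]
        for (t_key in common[order(tot, abs(as.integer(common)))]) {
          t <- as.integer(t_key)
          pa <- trace_path(spa$pred, t)   # a ... t
          pb <- trace_path(spb$pred, t)   # b ... t
          ia <- setdiff(head(pa, -1), integer(0))  # interiors incl a, excl t
          ib <- setdiff(head(pb, -1), integer(0))
          if (t == a) ia <- integer(0)
          if (t == b) ib <- integer(0)
          if (length(intersect(abs(ia), abs(ib)))) next
          if (abs(t) %in% c(abs(ia), abs(ib))) next
          inner_a <- branch_sequence(g, ia)
          inner_b <- branch_sequence(g, ib)
          if (abs(nchar(inner_a) - nchar(inner_b)) > max_len_diff) next
          if (path_identity(inner_a, inner_b) < min_identity) next
          cand <- list(s = s, t = t, path_a = ia, path_b = ib)
          if (!is.null(ok <- orient_bubble(g, cand))) return(ok)
        }
      }
    }
  }
  NULL
}

# decide winner/loser by interior coverage; refuse entangled losers
orient_bubble <- function(g, cand) {
  cov_of <- function(p) {
    if (!length(p)) return(0)
    len <- g$nodes$length[abs(p)] - (g$k - 1)
    sum(g$nodes$coverage[abs(p)] * len) / sum(len)
  }
  ca <- cov_of(cand$path_a); cb <- cov_of(cand$path_b)
  if (ca >= cb) { win <- cand$path_a; lose <- cand$path_b }
  else { win <- cand$path_b; lose <- cand$path_a }
  if (!length(lose)) return(NULL)  # cannot remove a direct edge's branch
  dir <- directed_edges(g)
  allowed <- c(cand$s, lose, cand$t)
  for (u in lose) {
    inc <- dir[abs(dir$from) == abs(u) | abs(dir$to) == abs(u), , drop = FALSE]
    others <- unique(c(inc$from, inc$to, -inc$from, -inc$to))
    if (!all(abs(others) %in% abs(allowed))) return(NULL)
  }
  list(s = cand$s, t = cand$t, win = win, lose = lose,
       win_cov = max(ca, cb), lose_cov = min(ca, cb))
}

pop_bubble <- function(g, hit) {
  if (length(hit$win))
    g$nodes$coverage[abs(hit$win)] <- g$nodes$coverage[abs(hit$win)] +
      hit$lose_cov
  drop_nodes(g, abs(hit$lose))
}

drop_nodes <- function(g, drop) {
  if (!length(drop)) return(g)
  keep <- !(abs(g$edges$from) %in% drop | abs(g$edges$to) %in% drop)
  g$edges <- g$edges[keep, , drop = FALSE]
  old_ids <- setdiff(g$nodes$node, drop)
  remap <- setNames(seq_along(old_ids), old_ids)
  g$nodes <- g$nodes[g$nodes$node %in% old_ids, , drop = FALSE]
  g$nodes$node <- seq_len(nrow(g$nodes))
  if (nrow(g$edges)) {
    g$edges$from <- as.integer(sign(g$edges$from) * remap[as.character(abs(g$edges$from))])
    g$edges$to <- as.integer(sign(g$edges$to) * remap[as.character(abs(g$edges$to))])
  }
  g$edges <- normalize_edges(g$edges)
  g
}

#' Simplify the merged graph and emit contigs
#'
#' Removes node-level tips (a node dead-ended on one side, shorter than
#' `2k` bases, attached to a node that branches on the facing side) and
#' low-coverage nodes (below `min_coverage`, default half the median node
#' coverage), then concatenates maximal linear node runs, collapsing the
#' `k - 1` base overlaps. Contigs are reported on the canonical strand (one
#' strand per twin pair), sorted, and filtered to `min_len` bases.
#'
#' @param g a `seq_graph` after [merge_bubbles()].
#' @param min_len minimum contig length to report (default 100).
#' @param min_coverage low-coverage node cutoff; `NULL` for the adaptive
#'   default.
#' @return tibble with `contig`, `sequence`, `length`, `coverage`.
#' @export
finalize_contigs <- function(g, min_len = 100, min_coverage = NULL) {
  stopifnot(inherits(g, "seq_graph"))
  k <- g$k
  # node-level tip clipping
  repeat {
    if (nrow(g$nodes) == 0) break
    dir <- directed_edges(g)
    tip <- NULL
    for (n in g$nodes$node) {
      if (g$nodes$length[n] >= 2 * k) next
      for (u in c(n, -n)) {
        indeg <- sum(dir$to == u)
        outs <- dir$to[dir$from == u]
        if (indeg != 0 || length(outs) == 0) next
        junction <- any(vapply(outs, function(v) sum(dir$to == v) >= 2,
                               logical(1)))
        if (junction) { tip <- n; break }
      }
      if (!is.null(tip)) break
    }
    if (is.null(tip)) break
    g <- drop_nodes(g, tip)
  }
  # low-coverage node removal
  if (nrow(g$nodes)) {
    cutoff <- if (is.null(min_coverage)) 0.5 * median(g$nodes$coverage)
              else min_coverage
    low <- g$nodes$node[g$nodes$coverage < cutoff]
    g <- drop_nodes(g, low)
  }
  if (nrow(g$nodes) == 0)
    return(tibble(contig = integer(0), sequence = character(0),
                  length = integer(0), coverage = numeric(0)))
  # concatenate maximal linear runs
  dir <- directed_edges(g)
  succ_of <- function(u) {
    outs <- dir$to[dir$from == u]
    if (length(outs) != 1) return(NA_integer_)
    v <- outs[1]
    if (sum(dir$to == v) != 1) return(NA_integer_)
    v
  }
  ord <- g$nodes$node[order(g$nodes$sequence)]
  visited <- rep(FALSE, nrow(g$nodes))
  runs <- list()
  for (n in ord) {
    for (u in c(n, -n)) {
      if (visited[n]) next
      preds <- dir$from[dir$to == u]
      is_start <- !(length(preds) == 1 && identical(succ_of(preds[1]), u))
      if (!is_start) next
      run <- u
      visited[n] <- TRUE
      v <- succ_of(u)
      while (!is.na(v) && !visited[abs(v)]) {
        run <- c(run, v)
        visited[abs(v)] <- TRUE
        v <- succ_of(v)
      }
      runs[[length(runs) + 1]] <- run
    }
  }
  # leftover pure cycles
  for (n in ord) {
    if (visited[n]) next
    run <- n
    visited[n] <- TRUE
    v <- succ_of(n)
    while (!is.na(v) && !visited[abs(v)]) {
      run <- c(run, v)
      visited[abs(v)] <- TRUE
      v <- succ_of(v)
    }
    runs[[length(runs) + 1]] <- run
  }
  seqs <- vapply(runs, function(run) {
    paste(c(node_seq(g, run[1]),
            vapply(run[-1], function(u) node_contrib(g, u), character(1))),
          collapse = "")
  }, character(1))
  covs <- vapply(runs, function(run) {
    len <- g$nodes$length[abs(run)]
    sum(g$nodes$coverage[abs(run)] * len) / sum(len)
  }, numeric(1))
  out <- tibble(sequence = canonical_chr(seqs), coverage = covs) %>%
    mutate(length = nchar(.data$sequence)) %>%
    filter(.data$length >= min_len) %>%
    arrange(.data$sequence) %>%
    mutate(contig = row_number()) %>%
    select("contig", "sequence", "length", "coverage")
  out
}

#' Write contigs to FASTA
#' @param contigs tibble from [finalize_contigs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  ids <- sprintf("contig_%d cov=%.1f len=%d", contigs$contig,
                 contigs$coverage, contigs$length)
  write_fasta(setNames(contigs$sequence, ids), path)
}
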