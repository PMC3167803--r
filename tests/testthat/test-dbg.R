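# brute-force oracle: the adjacency mask each canonical k-mer should carry,
# rebuilt from read windows by string arithmetic alone
o_adjacency <- function(reads, k) {
  bits <- list()
  setbit <- function(km, b) {
    cur <- bits[[km]]
    if (is.null(cur)) cur <- rep(FALSE, 8)
    cur[b + 1] <- TRUE
    bits[[km]] <<- cur
  }
  code <- function(b) match(b, BASES4) - 1L
  comp <- function(b) chartr("ACGT", "TGCA", b)
  for (rd in reads) {
    n <- nchar(rd)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      obs <- substr(rd, i, i + k - 1)
      can <- o_canonical(obs)
      fwd <- obs == can
      left <- if (i > 1) substr(rd, i - 1, i - 1) else NA
      right <- if (i + k <= n) substr(rd, i + k, i + k) else NA
      if (!is.na(right)) setbit(can, if (fwd) code(right) else 4 + code(right))
      if (!is.na(left)) setbit(can, if (fwd) 4 + code(comp(left))
                               else code(comp(left)))
    }
  }
  vapply(bits, function(v) sum(2^(which(v) - 1)), numeric(1))
}

store_masks <- function(st) {
  td <- tidy(st)
  setNames(as.numeric(td$adjacency), td$kmer)
}

test_that("read adjacency sets exactly the oracle's linkage bits", {
  set.seed(20)
  cases <- list(list(reads = "ACGTT", k = 3),
                list(reads = replicate(10, rand_seq(30)), k = 5),
                list(reads = tile_reads(rand_seq(300), step = 3), k = 11))
  for (cs in cases) {
    st <- count_kmers(cs$reads, cs$k)
    add_read_linkages(st, cs$reads)
    want <- o_adjacency(cs$reads, cs$k)
    got <- store_masks(st)
    expect_equal(got[sort(names(got))], want[sort(names(want))])
    expect_true(check_edge_symmetry(st))
  }
})

test_that("a read of length exactly k creates no linkage", {
  st <- count_kmers("ACGTACG", 7)
  add_read_linkages(st, "ACGTACG")
  expect_equal(tidy(st)$adjacency, 0L)
})

test_that("linkages are strand-symmetric: rc'd reads give identical masks", {
  set.seed(21)
  reads <- replicate(15, rand_seq(40))
  st1 <- count_kmers(reads, 9); add_read_linkages(st1, reads)
  st2 <- count_kmers(o_rc(reads), 9); add_read_linkages(st2, o_rc(reads))
  expect_equal(store_masks(st1), store_masks(st2))
})

test_that("linkage construction on unseen reads is a consistency error", {
  st <- count_kmers("ACGTACGTAC", 7)
  expect_error(add_read_linkages(st, "TTTTTTTT"), "absent from the store")
})

test_that("the multiplicity threshold sits in the spectrum valley", {
  # bimodal: error mode at 1, coverage mode near 30, valley at 4
  m30 <- round(600 * exp(-((10:40) - 30)^2 / 40))
  h <- tibble::tibble(
    multiplicity = 1:40,
    count = c(1000, 300, 80, 25, 30, 120, 250, 400, 480, m30))
  expect_equal(estimate_m(h), 4L)
  # strictly decreasing: no coverage peak, conservative fallback
  h2 <- tibble::tibble(multiplicity = 1:20, count = 2000 %/% (1:20)^2)
  expect_equal(estimate_m(h2), 2L)
  # clean high-coverage spectrum: threshold must spare every true k-mer
  h3 <- tibble::tibble(multiplicity = 10:50,
                       count = round(500 * exp(-((10:50) - 30)^2 / 50)))
  expect_lte(estimate_m(h3), 10L)
  expect_error(estimate_m(tibble::tibble(multiplicity = integer(),
                                         count = integer())), "empty")
})

test_that("one erroneous read end is cleaned away entirely", {
  set.seed(22)
  g <- rand_seq(300)
  clean <- tile_reads(g, rl = 30, step = 1)
  bad <- substr(g, 100, 129)
  substr(bad, 28, 30) <- "AAA"  # error burst at the read end
  if (substr(bad, 28, 30) == substr(g, 127, 129)) substr(bad, 28, 30) <- "CCC"
  dirty <- c(clean, bad)
  st <- count_kmers(dirty, 15)
  add_read_linkages(st, dirty)
  st <- remove_low_frequency_dead_ends(st, m = 5)
  # the reference is the clean read set pushed through the same filter:
  # genome-terminal k-mers sit below m in both and go either way
  ref <- count_kmers(clean, 15)
  add_read_linkages(ref, clean)
  ref <- remove_low_frequency_dead_ends(ref, m = 5)
  expect_equal(sort(tidy(st)$kmer), sort(tidy(ref)$kmer))
  expect_true(check_edge_symmetry(st))
})

test_that("clean graphs pass the dead-end filter untouched", {
  set.seed(23)
  g <- rand_seq(200)
  reads <- tile_reads(g, rl = 25, step = 1)
  st <- count_kmers(reads, 11)
  add_read_linkages(st, reads)
  n0 <- store_size(st)
  st <- remove_low_frequency_dead_ends(st, m = 2)
  expect_equal(store_size(st), n0)
  expect_equal(attr(st, "removed"), 0L)
})

test_that("a hanging low-multiplicity chain is consumed over multiple rounds", {
  set.seed(24)
  g <- rand_seq(120)
  k <- 11
  clean <- tile_reads(g, rl = 25, step = 1)
  # one read wanders off the genome mid-way: its tail forms a dangling chain
  bad <- paste0(substr(g, 50, 50 + k - 1), "GATTACA")
  dirty <- c(clean, bad)
  st <- count_kmers(dirty, k)
  add_read_linkages(st, dirty)
  st <- remove_low_frequency_dead_ends(st, m = 3)
  expect_gte(attr(st, "rounds"), 2)
  ref <- count_kmers(clean, k)
  add_read_linkages(ref, clean)
  ref <- remove_low_frequency_dead_ends(ref, m = 3)
  expect_equal(sort(tidy(st)$kmer), sort(tidy(ref)$kmer))
})

# backbone plus a divergent branch of `extra` novel bases hanging off the
# anchor at position j; the branch chain spans extra + k - 1 bases
branch_fixture <- function(k, extra, seed) {
  set.seed(seed)
  repeat {
    g <- rand_seq(200)
    j <- 80
    anchor <- substr(g, j, j + k - 1)
    branch <- paste0(anchor, rand_seq(extra))
    reads <- c(tile_reads(g, rl = 2 * k + 4, step = 1),
               tile_reads(branch, rl = min(nchar(branch), 2 * k + 4),
                          step = 1))
    st <- count_kmers(reads, k)
    n_new <- store_size(st) - store_size(count_kmers(
      tile_reads(g, rl = 2 * k + 4, step = 1), k))
    if (n_new == extra) break  # branch k-mers are all novel; no collisions
  }
  add_read_linkages(st, reads)
  list(store = st, genome = g)
}

test_that("tips shorter than 2k are clipped; 2k-base tips are released", {
  k <- 11
  fx <- branch_fixture(k, extra = k, seed = 25)      # 2k - 1 bases: a tip
  st <- remove_tips(fx$store)
  expect_equal(attr(st, "tips_removed"), 1L)
  ref <- count_kmers(tile_reads(fx$genome, rl = 2 * k + 4, step = 1), k)
  expect_equal(sort(tidy(st)$kmer), sort(tidy(ref)$kmer))
  expect_true(check_edge_symmetry(st))

  fx2 <- branch_fixture(k, extra = k + 1, seed = 26) # exactly 2k: released
  st2 <- remove_tips(fx2$store)
  expect_equal(attr(st2, "tips_removed"), 0L)
})

test_that("an isolated linear chain is a candidate contig, not a tip", {
  set.seed(27)
  g <- rand_seq(30)  # shorter than 2k for k = 11
  reads <- tile_reads(g, rl = 25, step = 1)
  st <- count_kmers(reads, 11)
  add_read_linkages(st, reads)
  n0 <- store_size(st)
  st <- remove_tips(st)
  expect_equal(attr(st, "tips_removed"), 0L)
  expect_equal(store_size(st), n0)
  ch <- extract_chains(st)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$sequence, o_canonical(g))
})

test_that("a branch-free graph compacts losslessly into one chain", {
  set.seed(28)
  g <- rand_seq(500)
  reads <- tile_reads(g, rl = 36, step = 2)
  st <- count_kmers(reads, 21)
  add_read_linkages(st, reads)
  ch <- extract_chains(st)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$sequence, o_canonical(g))
  expect_equal(ch$kmer_count, 500 - 21 + 1)
  expect_equal(ch$coverage, ch$mult_sum / 500)
})

test_that("a perfect cycle is broken once and emitted as one linear chain", {
  set.seed(29)
  k <- 11
  g <- rand_seq(80)
  circ <- paste0(g, substr(g, 1, 30))  # wrap so every adjacency is seen
  reads <- tile_reads(circ, rl = 30, step = 1, both = FALSE)
  st <- count_kmers(reads, k)
  add_read_linkages(st, reads)
  ch <- extract_chains(st)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$kmer_count, 80)          # each cyclic k-mer exactly once
  expect_equal(ch$length, 80 + k - 1)
})

test_that("chain extraction partitions the surviving k-mers", {
  set.seed(30)
  reads <- c(tile_reads(rand_seq(300), step = 2),
             tile_reads(rand_seq(150), step = 2))
  st <- count_kmers(reads, 13)
  add_read_linkages(st, reads)
  ch <- extract_chains(st)
  expect_equal(sum(ch$kmer_count), store_size(st))
})

test_that("chain output is invariant to the partition count", {
  set.seed(31)
  g <- rand_seq(2000)
  reads <- tile_reads(g, rl = 36, step = 1)
  outs <- lapply(c(1, 2, 4), function(np) {
    st <- count_kmers(reads, 15, n_parts = np, r = 10)
    add_read_linkages(st, reads)
    extract_chains(st)[c("sequence", "kmer_count", "mult_sum")]
  })
  expect_equal(outs[[2]], outs[[1]])
  expect_equal(outs[[3]], outs[[1]])
})

test_that("the dbg stage commutes with reverse-complementing the read set", {
  set.seed(32)
  g <- rand_seq(600)
  reads <- tile_reads(g, rl = 30, step = 2, both = FALSE)
  run <- function(rr) {
    st <- count_kmers(rr, 13)
    add_read_linkages(st, rr)
    st <- remove_low_frequency_dead_ends(st, m = 2)
    st <- remove_tips(st)
    extract_chains(st)[c("sequence", "kmer_count")]
  }
  expect_equal(run(reads), run(o_rc(reads)))
})

test_that("low-coverage chains are flagged as discarded, not silently dropped", {
  set.seed(33)
  g1 <- rand_seq(200)
  g2 <- rand_seq(60)
  reads <- c(tile_reads(g1, rl = 30, step = 1),   # deep
             substr(g2, 1, 30))                   # one stray read
  st <- count_kmers(reads, 11)
  add_read_linkages(st, reads)
  ch <- extract_chains(st, min_coverage = 2)
  expect_equal(nrow(ch), 2)
  expect_true(any(ch$kept) && any(!ch$kept))
  expect_equal(sum(ch$kmer_count), store_size(st))
})
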