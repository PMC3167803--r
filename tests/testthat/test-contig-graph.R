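test_that("a read spanning two unitigs creates one supported edge", {
  set.seed(40)
  k <- 11
  g <- rand_seq(120)
  u1 <- substr(g, 1, 60)
  u2 <- substr(g, 61 - k + 1, 120)  # k-1 overlap with u1
  span <- substr(g, 45, 80)
  sg <- build_sequence_graph(c(u1, u2), span, k)
  expect_equal(nrow(sg$edges), 1)
  expect_equal(sg$edges$support, 1L)
  # threading the same read again updates the edge, it does not duplicate it
  sg2 <- build_sequence_graph(c(u1, u2), c(span, span), k)
  expect_equal(nrow(sg2$edges), 1)
  expect_equal(sg2$edges$support, 2L)
  # twin symmetry: reverse-complemented reads give the same graph
  sg3 <- build_sequence_graph(c(u1, u2), o_rc(span), k)
  expect_equal(sg3$edges, sg$edges)
})

test_that("reads with no k-mer in any node are skipped silently", {
  set.seed(41)
  sg <- build_sequence_graph(rand_seq(50), rand_seq(30), 11)
  expect_equal(nrow(sg$edges), 0)
})

# a source/sink pair with two parallel branches whose inner sequences are
# fully controlled; nodes overlap their neighbours by k-1 bases
bubble_fixture <- function(inner_a, inner_b, k = 11, cov = c(1, 10, 5, 1)) {
  set.seed(nchar(inner_a) + nchar(inner_b))
  s <- rand_seq(3 * k)
  t <- rand_seq(3 * k)
  ov <- substr(s, nchar(s) - k + 2, nchar(s))
  b1 <- paste0(ov, inner_a)
  b2 <- paste0(ov, inner_b)
  nodes <- tibble::tibble(sequence = c(s, b1, b2, t), coverage = cov)
  edges <- tibble::tibble(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4),
                          support = 5L)
  seq_graph(nodes, edges, k)
}

mutate_at_pos <- function(s, pos) {
  for (p in pos) {
    old <- substr(s, p, p)
    substr(s, p, p) <- setdiff(BASES4, old)[1]
  }
  s
}

test_that("bubble merging honours the exact decision boundary", {
  set.seed(42)
  # with k = 11 the branch sequence spans 10 + 90 = 100 bases, so identity
  # percentages are exact counts of mismatched bases
  x <- rand_seq(90)

  # equal length, one mismatch (99% identity): merged
  g1 <- merge_bubbles(bubble_fixture(x, mutate_at_pos(x, 20)),
                      max_depth = 200)
  expect_equal(attr(g1, "merged"), 1L)
  expect_equal(nrow(g1$nodes), 3)

  # delta-len 2 with identity exactly 90/100: merged (inclusive boundary)
  y <- mutate_at_pos(substr(x, 1, 88), c(10, 20, 30, 40, 50, 60, 70, 80))
  g2 <- merge_bubbles(bubble_fixture(x, y), max_depth = 200)
  expect_equal(attr(g2, "merged"), 1L)

  # delta-len 3, identity ~97%: NOT merged (length criterion)
  g3 <- merge_bubbles(bubble_fixture(x, substr(x, 1, 87)), max_depth = 200)
  expect_equal(attr(g3, "merged"), 0L)
  expect_equal(nrow(g3$nodes), 4)

  # equal length, identity 89/100 < 90%: NOT merged
  g4 <- merge_bubbles(bubble_fixture(x, mutate_at_pos(x, 8 * (1:11))),
                      max_depth = 200)
  expect_equal(attr(g4, "merged"), 0L)
})

test_that("the lower-coverage branch loses and its coverage is folded in", {
  set.seed(43)
  x <- rand_seq(40)
  g <- bubble_fixture(x, mutate_at_pos(x, 7), cov = c(1, 10, 4, 1))
  keep_seq <- g$nodes$sequence[2]  # branch with coverage 10 wins
  m <- merge_bubbles(g)
  expect_true(keep_seq %in% m$nodes$sequence)
  expect_equal(m$nodes$coverage[m$nodes$sequence == keep_seq], 14)
})

test_that("merging preserves twin symmetry and total content accounting", {
  set.seed(44)
  x <- rand_seq(40)
  g <- bubble_fixture(x, mutate_at_pos(x, 15))
  m <- merge_bubbles(g)
  e <- m$edges
  # normalized storage admits each edge once; expanding twins stays closed
  d <- rbind(e, data.frame(from = -e$to, to = -e$from, support = e$support))
  expect_true(all(paste(-d$to, -d$from) %in% paste(d$from, d$to)))
  lost <- sum(g$nodes$length) - sum(m$nodes$length)
  expect_equal(lost, nchar(x) + g$k - 1)  # exactly the popped branch
})

test_that("error-free single-sequence graphs emit the genome unchanged", {
  set.seed(45)
  g <- rand_seq(400)
  reads <- tile_reads(g, rl = 36, step = 2)
  st <- count_kmers(reads, 15)
  add_read_linkages(st, reads)
  ch <- extract_chains(st)
  sg <- build_sequence_graph(ch, reads, 15)
  m <- merge_bubbles(sg)
  expect_equal(attr(m, "merged"), 0L)  # nothing to merge on clean data
  contigs <- finalize_contigs(m)
  expect_equal(nrow(contigs), 1)
  expect_equal(contigs$sequence, o_canonical(g))
})

test_that("contig reporting applies the 100-base minimum length", {
  set.seed(46)
  n99 <- rand_seq(99)
  n100 <- rand_seq(100)
  g <- seq_graph(c(n99, n100), NULL, 11)
  contigs <- finalize_contigs(g, min_coverage = 0)
  expect_equal(nrow(contigs), 1)
  expect_equal(contigs$length, 100L)
})

test_that("node-level tips at a branch are clipped before contig emission", {
  set.seed(47)
  k <- 11
  g <- rand_seq(300)
  main1 <- substr(g, 1, 150)
  main2 <- substr(g, 151 - k + 1, 300)
  stub <- paste0(substr(main1, 150 - k + 2, 150), rand_seq(5))  # 15 < 2k
  nodes <- tibble::tibble(sequence = c(main1, main2, stub),
                          coverage = c(10, 10, 1))
  edges <- tibble::tibble(from = c(1, 1), to = c(2, 3), support = c(9L, 1L))
  contigs <- finalize_contigs(seq_graph(nodes, edges, k), min_coverage = 0)
  expect_equal(nrow(contigs), 1)
  expect_equal(contigs$length, 300L)   # stub removed, main path concatenated
})

test_that("low-coverage nodes are dropped under the adaptive cutoff", {
  set.seed(48)
  nodes <- tibble::tibble(sequence = c(rand_seq(200), rand_seq(200),
                                       rand_seq(200)),
                          coverage = c(20, 22, 1))
  contigs <- finalize_contigs(seq_graph(nodes, NULL, 11))
  expect_equal(nrow(contigs), 2)
})
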