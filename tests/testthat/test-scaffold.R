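# simulate reads over a genome, cut known contigs out of it, and map pairs
scaffold_fixture <- function(genome_length = 6000, cut = c(3000, 3151),
                             insert_mean = 400, insert_sd = 40, seed = 50,
                             coverage = 30) {
  cfg <- sim_config(genome_length = genome_length, coverage = coverage,
                    insert_mean = insert_mean, insert_sd = insert_sd,
                    seed = seed)
  g <- simulate_genome(cfg, repeat_free_k = 21)
  sim <- simulate_pairs(g, cfg)
  contigs <- tibble::tibble(
    sequence = c(substr(g, 1, cut[1]), substr(g, cut[2], genome_length)))
  contigs$length <- nchar(contigs$sequence)
  contigs$contig <- seq_len(nrow(contigs))
  list(genome = g, sim = sim, contigs = contigs, cfg = cfg)
}

test_that("pair mapping records same-contig and cross-contig pairs", {
  fx <- scaffold_fixture()
  db <- map_pairs(fx$contigs, fx$sim$pairs$read_1, fx$sim$pairs$read_2, 21)
  expect_gt(nrow(db), 1000)
  same <- db[db$contig_1 == db$contig_2, ]
  cross <- db[db$contig_1 != db$contig_2, ]
  expect_gt(nrow(same), 1000)
  expect_gt(nrow(cross), 10)
  # mapped coordinates reproduce the simulated fragment starts
  j <- match(same$pair, fx$sim$truth$pair)
  left_mate <- ifelse(same$strand_1 > 0, same$start_1, same$start_2)
  contig_off <- ifelse(same$contig_1 == 2, fx$contigs$length[1] + 150, 0)
  truth0 <- fx$sim$truth$start[j] - 1 - contig_off  # 0-based on the contig
  frac_exact <- mean(left_mate == truth0)
  expect_gt(frac_exact, 0.95)  # only end-truncated fragments may differ
})

test_that("a mate matching two contigs equally is ambiguous and dropped", {
  set.seed(51)
  s <- rand_seq(300)
  twin_contigs <- c(s, paste0(rand_seq(150), s))  # s occurs in both
  rd <- substr(s, 100, 135)
  db <- map_pairs(tibble::tibble(sequence = twin_contigs), rd, o_rc(rd), 21)
  expect_equal(nrow(db), 0)
})

test_that("unpaired input is an input-format error", {
  expect_error(map_pairs(tibble::tibble(sequence = rand_seq(200)),
                         c("ACGT", "ACGT"), "ACGT", 21),
               "unpaired")
})

test_that("insert statistics come from same-contig pairs only", {
  # degenerate: every span exactly 200
  db <- tibble::tibble(pair = 1:150, library = "libA",
                       contig_1 = 1L, strand_1 = 1L,
                       start_1 = seq(0, by = 3, length.out = 150), len_1 = 36L,
                       contig_2 = 1L, strand_2 = -1L,
                       start_2 = seq(0, by = 3, length.out = 150) + 164L,
                       len_2 = 36L)
  st <- estimate_insert_stats(db)
  expect_equal(st$median_insert, 200)
  expect_equal(st$insert_sd, 0)
  expect_equal(st$n_pairs, 150L)
  # too few pairs is an error naming the library
  expect_error(estimate_insert_stats(db[1:50, ]), "libA")
})

test_that("insert estimation recovers the simulated library model", {
  # 10^4 same-contig pairs at insert ~ normal(200, 20)
  cfg <- sim_config(genome_length = 48000, coverage = 30, seed = 52)
  g <- simulate_genome(cfg)
  sim <- simulate_pairs(g, cfg)
  db <- map_pairs(tibble::tibble(sequence = g),
                  sim$pairs$read_1, sim$pairs$read_2, 21)
  expect_gt(nrow(db), 1e4)
  st <- estimate_insert_stats(db)
  expect_gte(st$median_insert, 198)
  expect_lte(st$median_insert, 202)
  expect_gte(st$insert_sd, 18)
  expect_lte(st$insert_sd, 22)
})

test_that("a link needs at least three supporting pairs", {
  mk_db <- function(n) {
    tibble::tibble(pair = seq_len(n), library = "lib1",
                   contig_1 = 1L, strand_1 = 1L,
                   start_1 = 960L + seq_len(n), len_1 = 36L,
                   contig_2 = 2L, strand_2 = -1L,
                   start_2 = 90L + seq_len(n), len_2 = 36L) -> db
    attr(db, "contig_lengths") <- c(1000L, 1000L)
    db
  }
  stats <- tibble::tibble(library = "lib1", n_pairs = 500L,
                          median_insert = 200, insert_sd = 20)
  expect_equal(nrow(build_links(mk_db(2), stats)), 0)
  l3 <- build_links(mk_db(3), stats)
  expect_equal(nrow(l3), 1)
  expect_equal(l3$n_pairs, 3L)
  # the threshold is monotone: lowering it never removes links
  expect_equal(nrow(build_links(mk_db(2), stats, min_pairs = 2)), 1)
  expect_equal(nrow(build_links(mk_db(3), stats, min_pairs = 4)), 0)
})

test_that("contradictory orientations form separate links, never one", {
  db <- tibble::tibble(pair = 1:6, library = "lib1",
                       contig_1 = 1L, strand_1 = c(1L, 1L, 1L, -1L, -1L, -1L),
                       start_1 = 950L, len_1 = 36L,
                       contig_2 = 2L, strand_2 = c(-1L, -1L, -1L, 1L, 1L, 1L),
                       start_2 = 100L, len_2 = 36L)
  attr(db, "contig_lengths") <- c(1000L, 1000L)
  stats <- tibble::tibble(library = "lib1", n_pairs = 500L,
                          median_insert = 200, insert_sd = 20)
  links <- build_links(db, stats)
  expect_equal(nrow(links), 2)
  expect_equal(sort(links$orientation), c("FF", "RR"))
})

test_that("gap estimates recover a known 150-base gap", {
  fx <- scaffold_fixture()
  db <- map_pairs(fx$contigs, fx$sim$pairs$read_1, fx$sim$pairs$read_2, 21)
  st <- estimate_insert_stats(db)
  links <- build_links(db, st)
  expect_equal(nrow(links), 1)
  expect_gte(links$n_pairs, 3)
  expect_equal(links$contig_a, 1L)
  expect_equal(links$side_a, "R")
  expect_equal(links$side_b, "L")
  expect_lt(abs(links$gap_estimate - 150), 15)
})

test_that("three contigs with consistent links form one ordered scaffold", {
  cfg <- sim_config(genome_length = 9000, coverage = 30, insert_mean = 400,
                    insert_sd = 40, seed = 53)
  g <- simulate_genome(cfg, repeat_free_k = 21)
  sim <- simulate_pairs(g, cfg)
  contigs <- tibble::tibble(sequence = c(substr(g, 1, 3000),
                                         substr(g, 3101, 6000),
                                         substr(g, 6121, 9000)))
  db <- map_pairs(contigs, sim$pairs$read_1, sim$pairs$read_2, 21)
  st <- estimate_insert_stats(db)
  links <- build_links(db, st)
  sc <- order_and_emit(links, contigs)
  expect_equal(nrow(sc), 1)
  lay <- attr(sc, "layout")
  expect_equal(lay$contig, c(1L, 2L, 3L))
  expect_equal(lay$orientation, c("F", "F", "F"))
  # scaffold length = contigs + rendered gaps; split inverts emission
  gaps <- round(pmax(1, lay$gap_after[1:2]))
  expect_equal(sc$length, sum(nchar(contigs$sequence)) + sum(gaps))
  expect_equal(split_scaffolds(sc)$sequence, contigs$sequence)
  # every contig appears exactly once across scaffolds
  expect_equal(sort(lay$contig), 1:3)
})

test_that("negative gap estimates render as a single N", {
  contigs <- tibble::tibble(sequence = c(rand_seq(200), rand_seq(200)))
  links <- tibble::tibble(contig_a = 1L, side_a = "R", contig_b = 2L,
                          side_b = "L", orientation = "FF", n_pairs = 10L,
                          gap_estimate = -12.4, gap_sd = 5)
  sc <- order_and_emit(links, contigs)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$length, 401L)
  expect_match(sc$sequence, "^[ACGT]{200}N[ACGT]{200}$")
  expect_equal(split_scaffolds(sc)$sequence, contigs$sequence)
})

test_that("unlinked contigs come out as singleton scaffolds, short ones suppressed", {
  contigs <- tibble::tibble(sequence = c(rand_seq(150), rand_seq(99)))
  sc <- order_and_emit(tibble::tibble(), contigs)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$n_contigs, 1L)
  expect_equal(sc$length, 150L)
})

test_that("a link closing a cycle is rejected and logged", {
  contigs <- tibble::tibble(sequence = c(rand_seq(200), rand_seq(200)))
  links <- tibble::tibble(
    contig_a = c(1L, 1L), side_a = c("R", "L"),
    contig_b = c(2L, 2L), side_b = c("L", "R"),
    orientation = "FF", n_pairs = c(10L, 4L),
    gap_estimate = 20, gap_sd = 5)
  sc <- order_and_emit(links, contigs)
  expect_equal(nrow(sc), 1)
  rej <- attr(sc, "rejected")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$n_pairs, 4L)  # the lower-support link lost
  lay <- attr(sc, "layout")
  expect_equal(sort(lay$contig), 1:2)
})
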