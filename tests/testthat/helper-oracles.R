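# Independent string-level oracles. Everything here is deliberately naive
# (substring arithmetic, hash-free, single table) so it shares no code path
# with the packed-code engine it checks.

BASES4 <- c("A", "C", "G", "T")

o_rc <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

o_canonical <- function(s) {
  r <- o_rc(s)
  ifelse(s <= r, s, r)
}

o_kmers <- function(read, k) {
  n <- nchar(read)
  if (n < k) return(character(0))
  substring(read, 1:(n - k + 1), k:n)
}

# canonical k-mer multiset over a read set
o_count <- function(reads, k) {
  km <- unlist(lapply(reads, o_kmers, k = k))
  if (!length(km)) return(integer(0))
  tab <- table(o_canonical(km))
  setNames(as.integer(tab), names(tab))
}

rand_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

rand_kmers <- function(n, k) {
  vapply(seq_len(n), function(i) rand_seq(k), character(1))
}

# tile a sequence with overlapping reads of length rl, both strands
tile_reads <- function(s, rl = 36, step = 4, both = TRUE) {
  n <- nchar(s)
  if (n < rl) return(character(0))
  starts <- unique(c(seq(1, n - rl + 1, by = step), n - rl + 1))
  fw <- substring(s, starts, starts + rl - 1)
  if (both) c(fw, o_rc(fw)) else fw
}

# Naive single-table de Bruijn unitig compaction: oriented k-mer strings,
# read-adjacency edges only, maximal 1-in/1-out chains. Returns canonical
# chain sequences, sorted. The reference for the partitioned engine.
o_compact <- function(reads, k) {
  succ <- new.env(parent = emptyenv())
  pred <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  note <- function(env, key, val) {
    cur <- env[[key]]
    if (is.null(cur)) env[[key]] <- val
    else if (!(val %in% cur)) env[[key]] <- c(cur, val)
  }
  for (rd in reads) {
    km <- o_kmers(rd, k)
    for (x in km) assign(x, TRUE, envir = seen)
    for (x in o_rc(km)) assign(x, TRUE, envir = seen)
    if (length(km) >= 2) {
      for (i in 1:(length(km) - 1)) {
        a <- km[i]; b <- km[i + 1]
        note(succ, a, b); note(pred, b, a)
        note(succ, o_rc(b), o_rc(a)); note(pred, o_rc(a), o_rc(b))
      }
    }
  }
  kmers <- ls(seen)
  ok_step <- function(a, b) {
    sa <- succ[[a]]; pb <- pred[[b]]
    !is.null(sa) && length(sa) == 1 && sa == b &&
      !is.null(pb) && length(pb) == 1 && pb == a
  }
  used <- new.env(parent = emptyenv())
  chains <- character(0)
  for (x in kmers) {
    if (!is.null(used[[x]])) next
    p <- pred[[x]]
    is_start <- is.null(p) || length(p) != 1 || !ok_step(p[1], x)
    if (!is_start) next
    chain <- x
    used[[x]] <- TRUE; used[[o_rc(x)]] <- TRUE
    cur <- x
    repeat {
      s <- succ[[cur]]
      if (is.null(s) || length(s) != 1 || !ok_step(cur, s[1])) break
      if (!is.null(used[[s[1]]])) break
      cur <- s[1]
      used[[cur]] <- TRUE; used[[o_rc(cur)]] <- TRUE
      chain <- c(chain, cur)
    }
    seqs <- paste0(chain[1],
                   paste(substring(chain[-1], k, k), collapse = ""))
    chains <- c(chains, o_canonical(seqs))
  }
  # pure cycles (nothing qualifies as a start): walk leftovers
  for (x in kmers) {
    if (!is.null(used[[x]])) next
    chain <- x
    used[[x]] <- TRUE; used[[o_rc(x)]] <- TRUE
    cur <- x
    repeat {
      s <- succ[[cur]]
      if (is.null(s) || length(s) != 1 || !is.null(used[[s[1]]])) break
      cur <- s[1]
      used[[cur]] <- TRUE; used[[o_rc(cur)]] <- TRUE
      chain <- c(chain, cur)
    }
    seqs <- paste0(chain[1],
                   paste(substring(chain[-1], k, k), collapse = ""))
    chains <- c(chains, o_canonical(seqs))
  }
  sort(chains)
}

# brute-force NGx exactly as the printed definition reads
o_ngx <- function(lengths, genome_size, x) {
  ls <- sort(lengths, decreasing = TRUE)
  total <- 0
  for (l in ls) {
    total <- total + l
    if (total > x / 100 * genome_size) return(l)
  }
  NA_real_
}

# an assembled sequence is correct iff it is an exact substring of the
# reference or of its reverse complement
o_exact_substring <- function(s, ref) {
  grepl(s, ref, fixed = TRUE) || grepl(s, o_rc(ref), fixed = TRUE)
}
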