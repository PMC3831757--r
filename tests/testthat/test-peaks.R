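test_that("deduplication keeps one read per start position and strand", {
  rd <- make_reads("chr1", c(101L, 101L, 101L, 201L),
                   strand = c("+", "+", "-", "+"))
  out <- deduplicate_reads(rd)
  expect_length(out, 3)  # same start, opposite strands both survive
  out2 <- deduplicate_reads(rd, strand_aware = FALSE)
  expect_length(out2, 2)

  # random multiset vs brute-force distinct-key count
  set.seed(21)
  n <- 400
  rnd <- make_reads(sample(c("chr1", "chr2"), n, replace = TRUE),
                    sample.int(50, n, replace = TRUE) * 10L,
                    strand = sample(c("+", "-"), n, replace = TRUE))
  key <- paste(GenomeInfoDb::seqnames(rnd), BiocGenerics::start(rnd),
               BiocGenerics::strand(rnd))
  expect_length(deduplicate_reads(rnd), length(unique(key)))
})

test_that("fragment extension covers exactly the expected interval", {
  sizes <- c(chr1 = 10000L)
  cfg <- peakcall_config(fragment_length = 170)
  # + read at 101: fragment occupies [101, 270]
  cov <- extend_and_pileup(make_reads("chr1", 101L), cfg, sizes)
  v <- as.integer(cov$chr1)
  expect_equal(which(v == 1L), 101:270)
  # - read ending at 550: fragment occupies [381, 550]
  cov <- extend_and_pileup(make_reads("chr1", 501L, strand = "-"), cfg, sizes)
  expect_equal(which(as.integer(cov$chr1) == 1L), 381:550)
  # no reads: all-zero coverage
  cov <- extend_and_pileup(make_reads("chr1", integer(0)), cfg, sizes)
  expect_true(all(as.integer(cov$chr1) == 0L))
})

test_that("pileup equals the brute-force interval-stabbing count", {
  set.seed(22)
  sizes <- c(chr1 = 10000L)
  cfg <- peakcall_config(fragment_length = 170)
  for (rep in 1:5) {
    n <- 200
    start <- sample.int(9951, n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rd <- make_reads("chr1", start, strand = strand)
    cov <- as.integer(extend_and_pileup(rd, cfg, sizes)$chr1)
    oracle <- oracle_pileup(start, start + 49L, strand, 170L, 10000L)
    expect_identical(cov, oracle)
    # conservation: total coverage equals summed clipped fragment lengths
    expect_equal(sum(cov), sum(oracle))
    expect_equal(sum(cov), sum(pmin(ifelse(strand == "+", start + 169L,
                                           start + 49L), 10000L) -
                               pmax(ifelse(strand == "+", start,
                                           start - 120L), 1L) + 1L))
  }
})

test_that("peak extraction matches brute-force run extraction", {
  set.seed(23)
  sizes <- c(chr1 = 2000L)
  cfg <- peakcall_config(fragment_length = 60, min_height = 3)
  for (rep in 1:20) {
    n <- sample(20:150, 1)
    start <- sample.int(1950, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rd <- deduplicate_reads(make_reads("chr1", start, width = 30L,
                                       strand = strand))
    cov <- extend_and_pileup(rd, cfg, sizes)
    pk <- call_peaks(cov, cfg, total_mapped = length(rd))
    oracle <- oracle_runs(as.integer(cov$chr1), 3L)
    if (is.null(oracle)) {
      expect_length(pk, 0)
    } else {
      expect_equal(BiocGenerics::start(pk), oracle$start)
      expect_equal(BiocGenerics::end(pk), oracle$end)
      expect_equal(pk$summit, oracle$summit)   # leftmost maximum
      expect_equal(pk$height, oracle$height)
    }
  }
})

test_that("a plateau peak takes its leftmost position as summit", {
  v <- integer(1000)
  v[500:599] <- 12L
  cov <- IRanges::RleList(chr1 = S4Vectors::Rle(v))
  pk <- call_peaks(cov, peakcall_config(min_height = 10), total_mapped = 1e6)
  expect_length(pk, 1)
  expect_equal(BiocGenerics::start(pk), 500L)
  expect_equal(BiocGenerics::end(pk), 599L)
  expect_equal(pk$summit, 500L)
  expect_equal(pk$height, 12L)
  expect_equal(pk$height_rpm, 12)
  # nothing above threshold: no peaks
  none <- call_peaks(cov, peakcall_config(min_height = 12))
  expect_length(none, 0)
  # threshold is strict by default, inclusive on request
  incl <- call_peaks(cov, peakcall_config(min_height = 12, inclusive = TRUE))
  expect_length(incl, 1)
})

test_that("peak calling is invariant under read order and monotone in threshold", {
  set.seed(24)
  sizes <- c(chr1 = 5000L)
  cfg5 <- peakcall_config(fragment_length = 100, min_height = 5)
  n <- 400
  start <- sample.int(4900, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  rd <- make_reads("chr1", start, strand = strand)
  perm <- sample.int(n)
  pk1 <- call_peaks(extend_and_pileup(deduplicate_reads(rd), cfg5, sizes), cfg5)
  pk2 <- call_peaks(extend_and_pileup(deduplicate_reads(rd[perm]), cfg5, sizes), cfg5)
  expect_identical(as.data.frame(pk1), as.data.frame(pk2))

  cov <- extend_and_pileup(deduplicate_reads(rd), cfg5, sizes)
  for (t in 5:9) {
    lo <- call_peaks(cov, peakcall_config(min_height = t))
    hi <- call_peaks(cov, peakcall_config(min_height = t + 1L))
    # stricter thresholds shrink the covered territory (a single run may
    # split into several, so base coverage, not peak count, is monotone)
    expect_lte(sum(BiocGenerics::width(hi)), sum(BiocGenerics::width(lo)))
    if (length(hi)) {
      # every stricter-threshold peak is contained in a looser one
      expect_true(all(IRanges::overlapsAny(hi, lo, type = "within")))
    }
  }
})

test_that("input filtering applies the summit-ratio rule exactly", {
  pk <- make_regions("chr1", c(100L, 500L), c(300L, 700L),
                     summit = c(200L, 600L), height = c(20L, 20L))
  inp <- integer(1000)
  inp[200] <- 10L  # 10 >= 0.25 * 20 -> removed
  inp[600] <- 4L   # 4 < 5 -> kept
  cov <- IRanges::RleList(chr1 = S4Vectors::Rle(inp))
  out <- suppressMessages(filter_by_input(pk, cov, peakcall_config()))
  expect_length(out, 1)
  expect_equal(out$summit, 600L)
  expect_equal(attr(out, "n_removed"), 1)

  # all-zero input keeps everything
  zero <- IRanges::RleList(chr1 = S4Vectors::Rle(integer(1000)))
  expect_length(suppressMessages(filter_by_input(pk, zero, peakcall_config())), 2)

  # random peaks and input against direct application of the inequality
  set.seed(25)
  n <- 200
  hp <- make_regions("chr1", seq(1, by = 40, length.out = n),
                     seq(30, by = 40, length.out = n),
                     summit = seq(10, by = 40, length.out = n),
                     height = sample(5:50, n, replace = TRUE))
  iv <- sample(0:20, 8000, replace = TRUE)
  icov <- IRanges::RleList(chr1 = S4Vectors::Rle(iv))
  kept <- suppressMessages(filter_by_input(hp, icov, peakcall_config()))
  manual <- iv[hp$summit] < 0.25 * hp$height
  expect_equal(length(kept), sum(manual))
  expect_equal(kept$summit, hp$summit[manual])
})

test_that("top-N capping rounds the smallest list down by thousands", {
  mk <- function(n) {
    set.seed(n)
    make_regions("chr1", seq_len(n) * 10L, seq_len(n) * 10L + 5L,
                 height_rpm = runif(n))
  }
  sets <- list(control = mk(10255L), patient = mk(10673L))
  capped <- select_top_peaks(sets, round_to = 1000L)
  expect_equal(vapply(capped, length, integer(1)),
               c(control = 10000L, patient = 10000L))
  expect_error(select_top_peaks(list(a = mk(999L), b = mk(2000L)),
                                round_to = 1000L), "round_to")

  # top-N equals brute-force sort-and-slice, ties broken by position
  set.seed(26)
  n <- 500
  gr <- make_regions("chr1", seq_len(n) * 20L, seq_len(n) * 20L + 10L,
                     height_rpm = sample(seq(0.5, 5, by = 0.5), n,
                                         replace = TRUE))
  top <- select_top_peaks(list(s = gr), round_to = 100L)$s
  ord <- order(-gr$height_rpm, BiocGenerics::start(gr))
  expect_identical(as.data.frame(top), as.data.frame(gr[ord[1:500]]))
})

test_that("E-box scanning equals a both-strand regex oracle", {
  set.seed(27)
  n <- 120
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 206, replace = TRUE),
          collapse = ""), character(1))
  # spike known motifs into some windows
  seqs[1] <- paste0(strrep("A", 70), "CACGTG", strrep("A", 130))
  seqs[2] <- paste0(strrep("T", 80), "CATGTG", strrep("T", 120))  # revcomp hit
  seqs[3] <- strrep("A", 206)
  genome <- Biostrings::DNAStringSet(setNames(seqs, paste0("w", seq_len(n))))
  pk <- make_regions(paste0("w", seq_len(n)), 50L, 160L, summit = 103L)
  hits <- scan_ebox(pk, genome, peakcall_config())$motif_hit_count
  for (i in seq_len(n)) {
    win <- substr(seqs[i], 103 - 50, 103 + 50 + 5)
    orc <- oracle_ebox(win)
    expect_equal(hits[i] >= 1, orc$hit, info = paste("window", i))
    expect_equal(hits[i], orc$count, info = paste("window", i))
  }
  expect_gte(hits[1], 1)
  expect_gte(hits[2], 1)
  expect_equal(hits[3], 0)
  sm <- ebox_summary(scan_ebox(pk, genome, peakcall_config()))
  expect_equal(sm$n_with_motif, sum(hits >= 1))
  expect_equal(sm$fraction, mean(hits >= 1))
})

test_that("the motif pattern set is closed under reverse complement", {
  pats <- peakcall_config()$motif_patterns
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(pats)))
  expect_setequal(pats, rc)
})
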