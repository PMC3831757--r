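test_that("peak-region union merges overlaps and records sources", {
  a <- make_regions("chr1", 101L, 200L)
  b <- make_regions("chr1", 151L, 250L)
  m <- merge_peak_regions(a, b)
  expect_length(m, 1)
  expect_equal(BiocGenerics::start(m), 101L)
  expect_equal(BiocGenerics::end(m), 250L)
  expect_equal(m$source, "both")
  only_c <- merge_peak_regions(a, make_regions("chr2", 900L, 950L))
  expect_equal(only_c$source[as.character(GenomeInfoDb::seqnames(only_c)) == "chr1"],
               "control")

  # random interval sets vs per-base union oracle
  set.seed(31)
  for (rep in 1:10) {
    s1 <- sample.int(1900, 30); s2 <- sample.int(1900, 30)
    g1 <- make_regions("chr1", s1, s1 + sample.int(80, 30))
    g2 <- make_regions("chr1", s2, s2 + sample.int(80, 30))
    m <- merge_peak_regions(g1, g2)
    orc <- oracle_union(c(s1, s2),
                        c(BiocGenerics::end(g1), BiocGenerics::end(g2)), 2100L)
    expect_equal(BiocGenerics::start(m), orc$start)
    expect_equal(BiocGenerics::end(m), orc$end)
  }
})

test_that("RPM counting matches its definition and is depth-linear", {
  reg <- make_regions("chr1", 1000L, 2000L)
  rd <- make_reads("chr1", c(960L, 1500L, 1990L, 2500L, 100L))
  expect_equal(count_rpm(reg, rd, total_mapped = 1e6), 3)
  expect_equal(count_rpm(make_regions("chr1", 5000L, 6000L), rd, 1e6), 0)
  expect_error(count_rpm(reg, rd, total_mapped = 0), "positive")

  # brute-force overlap counting on random data
  set.seed(32)
  rs <- sample.int(9000, 300)
  rd2 <- make_reads("chr1", rs)
  regs <- make_regions("chr1", seq(1, 9500, by = 500),
                       seq(1, 9500, by = 500) + 249L)
  got <- count_rpm(regs, rd2, total_mapped = 300)
  manual <- vapply(seq_along(regs), function(i) {
    sum(rs <= BiocGenerics::end(regs)[i] & rs + 49L >= BiocGenerics::start(regs)[i])
  }, numeric(1))
  expect_equal(got, manual * 1e6 / 300)
  # doubling depth with duplicated reads leaves RPM unchanged
  expect_equal(count_rpm(regs, c(rd2, rd2), total_mapped = 600), got)
})

test_that("difference ranking fills both directions with stable tie-breaks", {
  set.seed(33)
  n <- 50
  reg <- make_regions("chr1", seq_len(n) * 100L, seq_len(n) * 100L + 50L,
                      rpm_control = runif(n, 0, 10),
                      rpm_patient = runif(n, 0, 10))
  cfg <- differential_config(n_top = 10)
  rk <- rank_differential(reg, cfg)
  delta <- reg$rpm_patient - reg$rpm_control
  ordp <- order(-delta, BiocGenerics::start(reg))
  ordc <- order(delta, BiocGenerics::start(reg))
  expect_equal(BiocGenerics::start(rk$higher_in_patient),
               BiocGenerics::start(reg)[ordp[1:10]])
  expect_equal(BiocGenerics::start(rk$higher_in_control),
               BiocGenerics::start(reg)[ordc[1:10]])
  expect_equal(rk$higher_in_patient$rank, 1:10)
  expect_true(all(rk$higher_in_patient$delta >= 0 |
                  rk$higher_in_patient$rank > sum(delta > 0)))

  # swapping the samples swaps the two lists exactly
  swapped <- reg
  swapped$rpm_control <- reg$rpm_patient
  swapped$rpm_patient <- reg$rpm_control
  rk2 <- rank_differential(swapped, cfg)
  expect_equal(BiocGenerics::start(rk2$higher_in_patient),
               BiocGenerics::start(rk$higher_in_control))
  expect_equal(BiocGenerics::start(rk2$higher_in_control),
               BiocGenerics::start(rk$higher_in_patient))

  # identical columns: all deltas zero, lists filled in genomic order
  same <- reg
  same$rpm_patient <- same$rpm_control
  rk3 <- rank_differential(same, cfg)
  expect_true(all(rk3$higher_in_patient$delta == 0))
  expect_equal(BiocGenerics::start(rk3$higher_in_patient),
               sort(BiocGenerics::start(reg))[1:10])
  expect_warning(rank_differential(reg, differential_config(n_top = 100)),
                 "n_top")
})

test_that("nearest-TSS assignment matches exhaustive search", {
  genes <- test_genes()
  # midpoint exactly at a TSS
  at_tss <- nearest_tss(make_regions("chr1", 900L, 1100L), genes)
  expect_equal(at_tss$nearest_gene, "G1")
  expect_equal(at_tss$tss_distance, 0L)
  # equidistant between G1 (tss 1000) and G2 (tss 8000): smaller gene_id
  mid <- nearest_tss(make_regions("chr1", 4400L, 4600L), genes)
  expect_equal(mid$nearest_gene, "G1")
  # signs follow the gene's reading direction
  down_plus <- nearest_tss(make_regions("chr1", 1400L, 1600L), genes)
  expect_equal(down_plus$tss_distance, 500L)
  down_minus <- nearest_tss(make_regions("chr1", 7400L, 7600L), genes)
  expect_equal(down_minus$nearest_gene, "G2")
  expect_equal(down_minus$tss_distance, 500L)  # downstream on - strand
  expect_error(nearest_tss(make_regions("chr1", 1L, 10L), genes,
                           biotype = "miRNA"), "biotype")

  set.seed(34)
  sim <- simulate_study(tiny_config())
  n <- 60
  st <- sample.int(140000, n)
  regs <- make_regions("chr1", st, st + 200L)
  got <- nearest_tss(regs, sim$genes)
  for (i in seq_len(n)) {
    expect_equal(got$nearest_gene[i],
                 oracle_nearest("chr1", st[i] + 100L, sim$genes))
  }
})

test_that("genomic classification equals brute-force window and body tests", {
  genes <- test_genes()
  cfg <- differential_config()
  cls <- classify_regions(make_regions("chr1", 900L, 1100L), genes, cfg)
  expect_true(cls$tss_proximal)
  expect_true(cls$intragenic)
  lonely <- classify_regions(make_regions("chr9", 100L, 200L), genes, cfg)
  expect_false(lonely$tss_proximal)
  expect_false(lonely$intragenic)

  set.seed(35)
  n <- 100
  st <- sample.int(12000, n)
  regs <- make_regions("chr1", st, st + sample.int(300, n))
  cls <- classify_regions(regs, genes, cfg)
  g1 <- genes[genes$chrom == "chr1", ]
  for (i in seq_len(n)) {
    s <- st[i]; e <- BiocGenerics::end(regs)[i]
    exp_tss <- any(e >= g1$tss - 2000 & s <= g1$tss + 2000)
    exp_body <- any(e >= pmin(g1$tss, g1$tes) & s <= pmax(g1$tss, g1$tes))
    expect_equal(cls$tss_proximal[i], exp_tss)
    expect_equal(cls$intragenic[i], exp_body)
  }
})

test_that("repeat filtering removes regions above 80% coverage, strictly", {
  cfg <- differential_config()
  reps <- make_regions("chr1", c(101L, 401L), c(185L, 480L))
  # 100-bp region with 85 covered bases: removed
  r85 <- make_regions("chr1", 101L, 200L)
  expect_length(filter_simple_repeats(r85, reps, cfg), 0)
  # exactly 80 covered bases: retained
  r80 <- make_regions("chr1", 401L, 500L)
  expect_length(filter_simple_repeats(r80, reps, cfg), 1)

  # random regions vs per-base union-coverage oracle (overlapping repeats)
  set.seed(36)
  rs <- sample.int(5000, 40)
  reps2 <- make_regions("chr1", rs, rs + sample.int(400, 40))
  st <- sample.int(5000, 60)
  regs <- make_regions("chr1", st, st + sample.int(250, 60))
  kept <- filter_simple_repeats(regs, reps2, cfg)
  manual <- vapply(seq_along(regs), function(i) {
    oracle_repeat_frac(st[i], BiocGenerics::end(regs)[i], rs,
                       BiocGenerics::end(reps2))
  }, numeric(1))
  expect_equal(length(kept), sum(manual <= 0.8))
  expect_equal(BiocGenerics::start(kept), st[manual <= 0.8])
})

test_that("TSS footprints aggregate per-offset coverage, strand-oriented", {
  cfg <- differential_config(footprint_halfwidth = 1000)
  genes <- test_genes()[1, ]  # one + strand gene, tss 1000
  # one read covering exactly [tss, tss+49]
  fp <- tss_footprint(make_reads("chr1", 1000L), genes, cfg, mark = "m")
  expect_length(fp$values, 2001)
  expect_equal(which(fp$values == 1) - 1001L, 0:49)
  expect_equal(sum(fp$values), 50)
  # zero reads: zero vector
  fp0 <- tss_footprint(make_reads("chr1", integer(0)), genes, cfg)
  expect_equal(fp0$values, numeric(2001))
  # - strand gene: offsets are flipped into reading direction
  gminus <- test_genes()[2, ]  # tss 8000 on -
  fpm <- tss_footprint(make_reads("chr1", 8000L), gminus, cfg)
  expect_equal(which(fpm$values == 1) - 1001L, -49:0)
  fpm2 <- tss_footprint(make_reads("chr1", 8000L), gminus, cfg, flip = FALSE)
  expect_equal(which(fpm2$values == 1) - 1001L, 0:49)

  # random reads over 20 genes vs brute-force window extraction
  set.seed(37)
  sim <- simulate_study(tiny_config())
  pc <- sim$genes[sim$genes$biotype == "protein_coding", ]
  rd <- sim$reads$patient$H3K4me3
  fp <- tss_footprint(rd, sim$genes, cfg, mark = "H3K4me3")
  expect_equal(fp$n_genes, nrow(pc))
  covvec <- integer(sim$config$chrom_length)
  for (i in seq_along(rd)) {
    covvec[BiocGenerics::start(rd)[i]:BiocGenerics::end(rd)[i]] <-
      covvec[BiocGenerics::start(rd)[i]:BiocGenerics::end(rd)[i]] + 1L
  }
  acc <- numeric(2001)
  for (i in seq_len(nrow(pc))) {
    w <- covvec[(pc$tss[i] - 1000):(pc$tss[i] + 1000)]
    if (pc$strand[i] == "-") w <- rev(w)
    acc <- acc + w
  }
  expect_equal(fp$values, acc / nrow(pc))
})

test_that("footprint normalization satisfies its identities", {
  mkp <- function(vals, mark) footprint_profile(vals, mark, n_genes = 10)
  # single uniform profile: everything becomes exactly 1
  u <- normalize_footprints(list(mkp(rep(3.7, 2001), "u")))
  expect_equal(u[[1]]$values, rep(1, 2001))

  set.seed(38)
  profs <- list(mkp(runif(2001, 0, 5), "a"), mkp(runif(2001, 0, 2), "b"),
                mkp(runif(2001, 0, 9), "c"))
  norm <- normalize_footprints(profs)
  sums <- vapply(norm, function(p) sum(p$values), numeric(1))
  # equal sums (the step-1 identity survives the global rescale)...
  expect_lt(max(sums) - min(sums), 1e-9)
  # ...and the global maximum is exactly 1, attained by some mark
  gmax <- vapply(norm, function(p) max(p$values), numeric(1))
  expect_equal(max(gmax), 1)
  # idempotence
  norm2 <- normalize_footprints(norm)
  for (i in seq_along(norm)) {
    expect_equal(norm2[[i]]$values, norm[[i]]$values, tolerance = 1e-12)
  }
  # cross-mark ratios at each offset are preserved from step-1 output
  s1 <- lapply(profs, function(p) p$values * 2001 / sum(p$values))
  expect_equal(norm[[1]]$values / norm[[2]]$values, s1[[1]] / s1[[2]])
  expect_error(normalize_footprints(list(mkp(numeric(2001), "z"))),
               "sum-normalize")
})

test_that("gene peak presence recovers sample-specific planted peaks", {
  genes <- test_genes()
  cfg <- differential_config()
  pc <- make_regions("chr1", c(800L, 7800L), c(1200L, 8200L))   # G1+G2
  pp <- make_regions("chr1", 800L, 1200L)                        # G1 only
  pres <- peak_gene_presence(pc, pp, genes, cfg)
  expect_equal(pres, list(both = 1L, control_only = 1L, patient_only = 0L,
                          none = 1L))
  none <- peak_gene_presence(GenomicRanges::GRanges(),
                             GenomicRanges::GRanges(), genes, cfg)
  expect_equal(none$both + none$control_only + none$patient_only, 0L)

  # planted-site truth: presence computed from truth intervals agrees with
  # a brute-force per-gene window test
  sim <- simulate_study(tiny_config(seed = 14))
  s <- sim$sites[sim$sites$mark == "H3K4me3", ]
  grs <- function(sel) make_regions(s$chrom[sel], s$start[sel], s$end[sel])
  pc2 <- grs(s$presence %in% c("both", "control_only"))
  pp2 <- grs(s$presence %in% c("both", "patient_only"))
  pres2 <- peak_gene_presence(pc2, pp2, sim$genes, cfg)
  manual <- function(pk) vapply(seq_len(nrow(sim$genes)), function(i) {
    any(BiocGenerics::start(pk) <= sim$genes$tss[i] + 2000 &
        BiocGenerics::end(pk) >= sim$genes$tss[i] - 2000)
  }, logical(1))
  mc <- manual(pc2); mp <- manual(pp2)
  expect_equal(pres2$both, sum(mc & mp))
  expect_equal(pres2$control_only, sum(mc & !mp))
  expect_equal(pres2$patient_only, sum(!mc & mp))
})

test_that("TSS peak agreement: identity, disjointness, known correlation", {
  genes <- test_genes()
  cfg <- differential_config()
  set.seed(39)
  # peaks on a grid around the chr1 TSSs (spacing >> jitter, so the
  # nearest-summit matching is unambiguous)
  offs <- seq(-190L, 190L, by = 20L)
  sm <- c(1000L + offs, 8000L + offs)
  n <- length(sm)
  pk <- make_regions("chr1", sm - 50L, sm + 50L, summit = sm,
                     height = sample(10:100, n))
  self <- tss_peak_agreement(pk, pk, genes, cfg)
  expect_equal(self$r, 1)
  expect_equal(self$fraction_matched, 1)

  other <- make_regions("chr7", sm - 50L, sm + 50L, summit = sm,
                        height = pk$height)
  disj <- tss_peak_agreement(pk, other, genes, cfg)
  expect_equal(disj$fraction_matched, 0)
  expect_true(is.na(disj$r))

  # correlated heights: shared signal + noise, summits jittered < 100 bp
  rho_runs <- replicate(20, {
    base <- runif(n, 20, 120)
    ha <- base + rnorm(n, 0, 10)
    hb <- base + rnorm(n, 0, 10)
    pa <- make_regions("chr1", sm - 50L, sm + 50L, summit = sm, height = ha)
    pb <- make_regions("chr1", sm - 40L, sm + 60L,
                       summit = sm + sample(-5:5, n, replace = TRUE),
                       height = hb)
    c(tss_peak_agreement(pa, pb, genes, cfg)$r,
      cor(ha, hb))
  })
  # matched-pair correlation tracks the generating correlation
  expect_equal(mean(rho_runs[1, ]), mean(rho_runs[2, ]), tolerance = 0.1)
  expect_gt(min(rho_runs[1, ]), 0.5)
})
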