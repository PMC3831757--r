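## Synthetic study generator.
##
## Emulates the study design end to end with a recorded truth table: a
## random genome with planted E-box motifs, non-overlapping genes, simple
## repeats, two samples (control tissue, patient tissue) x three histone
## marks + one transcription factor with planted peaks, sample-specific
## presence and differential effects, Poisson background reads, an
## input-chromatin track with planted artifact regions, and variant /
## GWAS / LD / qPCR tables with per-record truth classes.

#' Simulation configuration
#'
#' Defaults describe the emulated study: two samples (control, patient)
#' assayed for H3K4me1, H3K4me3, H3K27ac and the E-box binding factor USF1;
#' 50 bp single-end reads extended to 170 bp fragments; the patient
#' libraries sequenced ~1.7x deeper than control.
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical outputs.
#' @param n_chrom,chrom_length Genome shape (default 2 x 400 kb).
#' @param n_genes Number of non-overlapping genes (default 80).
#' @param protein_coding_fraction Fraction annotated protein-coding
#'   (default 0.54, matching a genome where roughly half of annotated genes
#'   are protein coding).
#' @param n_repeats Number of simpleRepeat intervals (default 40).
#' @param marks Histone-mark names.
#' @param tf Transcription-factor track name.
#' @param n_peaks_hm,n_peaks_tf Planted sites per histone mark / for the TF.
#' @param peak_width_mean Mean planted site width in bp (default 300).
#' @param tss_fraction Named per-mark fraction of sites planted at gene
#'   TSSs (promoter-associated marks get more).
#' @param tf_tss_fraction Fraction of TF sites at TSSs.
#' @param shared_fraction,shared_fraction_tf Fraction of sites present in
#'   both samples; the rest split evenly into control-only / patient-only.
#' @param differential_fraction Fraction of shared histone sites given a
#'   fold asymmetry between samples.
#' @param differential_fold Fold change at differential sites (default 3).
#' @param site_height_sd,sample_noise_sd Log-normal SDs of the shared
#'   per-site height and of the per-sample height noise (defaults 0.3 and
#'   0.2); `sample_noise_sd = 0` makes non-differential sites exactly
#'   symmetric in expectation.
#' @param motif_fraction Fraction of TF sites with a planted E-box hexamer
#'   near the summit (default 0.5).
#' @param fragment_length,read_length Fragment and read lengths in bp
#'   (defaults 170 and 50).
#' @param background_rate Background read-start rate per bp (default 0.01).
#' @param peak_read_multiplier Read rate inside a planted site relative to
#'   background (default 20).
#' @param peak_base_rate Per-bp rate the multiplier applies to; defaults to
#'   `background_rate`. Setting it separately allows a zero-background
#'   genome that still carries planted peaks.
#' @param depth_factor Named per-sample library-depth multipliers for the
#'   histone-mark libraries (default control 1.0, patient 1.7: the patient
#'   histone libraries were the deeper ones).
#' @param tf_depth_factor Same for the TF track, where the relation is
#'   reversed (default control 1.0, patient 0.35); the per-sample pileup
#'   thresholds (10 control, 5 patient) compensate for this imbalance.
#' @param n_input_artifacts Regions enriched in input chromatin and in the
#'   TF ChIP of both samples (default 2); the input filter should remove
#'   them.
#' @param n_variants Planted variant sites (default 400).
#' @param known129_fraction Fraction present in the older variant
#'   catalogue (and in the newer one).
#' @param known132_only_fraction Fraction present only in the newer
#'   catalogue.
#' @param gwas_fraction Fraction of variants with a GWAS catalogue entry.
#' @param gwas_keyword_fraction Of those, fraction whose trait matches a
#'   study keyword.
#' @param ld_fraction Fraction of non-catalogue variants given an LD edge
#'   to a keyword-matching catalogue SNP.
#' @param ld_block_size Scale (bp) on which LD partner distances are drawn
#'   (default 500 kb; distances are drawn up to 1.6x this, so some planted
#'   edges exceed the proxy distance limit by design).
#' @param n_qpcr_pos,n_qpcr_neg qPCR regions at planted TF sites / at
#'   background (defaults 13 and 4, the validation design of the emulated
#'   study).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 0L, n_chrom = 2L, chrom_length = 400000L,
                       n_genes = 80L, protein_coding_fraction = 0.54,
                       n_repeats = 40L,
                       marks = c("H3K4me1", "H3K4me3", "H3K27ac"),
                       tf = "USF1",
                       n_peaks_hm = 50L, n_peaks_tf = 60L,
                       peak_width_mean = 300L,
                       tss_fraction = c(H3K4me1 = 0.15, H3K4me3 = 0.7,
                                        H3K27ac = 0.45),
                       tf_tss_fraction = 0.5,
                       shared_fraction = 0.7, shared_fraction_tf = 0.8,
                       differential_fraction = 0.4, differential_fold = 3,
                       site_height_sd = 0.3, sample_noise_sd = 0.2,
                       motif_fraction = 0.5,
                       fragment_length = 170L, read_length = 50L,
                       background_rate = 0.01, peak_read_multiplier = 20,
                       peak_base_rate = NULL,
                       depth_factor = c(control = 1.0, patient = 1.7),
                       tf_depth_factor = c(control = 1.0, patient = 0.35),
                       n_input_artifacts = 2L,
                       n_variants = 400L, known129_fraction = 0.5,
                       known132_only_fraction = 0.15,
                       gwas_fraction = 0.15, gwas_keyword_fraction = 0.6,
                       ld_fraction = 0.2, ld_block_size = 500000,
                       n_qpcr_pos = 13L, n_qpcr_neg = 4L) {
  cfg <- as.list(environment())
  fr <- c(protein_coding_fraction, shared_fraction, shared_fraction_tf,
          differential_fraction, motif_fraction, tss_fraction,
          tf_tss_fraction, known129_fraction, known132_only_fraction,
          gwas_fraction, gwas_keyword_fraction, ld_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1),
            known129_fraction + known132_only_fraction <= 1,
            n_chrom >= 1, chrom_length > 10 * peak_width_mean,
            fragment_length > 0, read_length > 0, background_rate >= 0,
            peak_read_multiplier >= 1, differential_fold >= 1,
            all(depth_factor > 0), all(tf_depth_factor > 0),
            all(c("control", "patient") %in% names(depth_factor)),
            all(c("control", "patient") %in% names(tf_depth_factor)),
            all(marks %in% names(tss_fraction)))
  structure(cfg, class = "sim_config")
}

## internal: place n non-overlapping intervals of given lengths on one
## chromosome with a minimum gap; error when they cannot fit
.place_nonoverlapping <- function(lengths, chrom_length, min_gap) {
  k <- length(lengths)
  if (k == 0) return(integer(0))
  need <- sum(lengths) + (k + 1) * min_gap
  if (need > chrom_length) {
    stop("genome too small: need ", need, " bp to place ", k,
         " features on a ", chrom_length, " bp chromosome")
  }
  slack <- chrom_length - need
  cuts <- sort(sample.int(slack + 1, k + 1, replace = TRUE) - 1L)
  gaps <- min_gap + diff(c(0L, cuts))        # k+1 gaps: before, between, after
  starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0L, lengths[-k])) + 1L
  as.integer(starts)
}

## internal: simulate genome sequence, genes, repeats
.sim_genome <- function(cfg) {
  chrom_names <- paste0("chr", seq_len(cfg$n_chrom))
  chrom_sizes <- setNames(rep(as.integer(cfg$chrom_length), cfg$n_chrom),
                          chrom_names)
  seqs <- Biostrings::DNAStringSet(vapply(chrom_names, function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(seqs) <- chrom_names

  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chrom + 1)))
  genes <- list()
  gid <- 0L
  for (i in seq_len(cfg$n_chrom)) {
    k <- per_chrom[i]
    if (k == 0) next
    lens <- sample(1500:4000, k, replace = TRUE)
    starts <- .place_nonoverlapping(lens, cfg$chrom_length, min_gap = 1500L)
    genes[[i]] <- data.frame(
      gene_id = sprintf("G%04d", gid + seq_len(k)),
      chrom = chrom_names[i],
      strand = sample(c("+", "-"), k, replace = TRUE),
      start = starts, end = starts + lens - 1L,
      biotype = ifelse(runif(k) < cfg$protein_coding_fraction,
                       "protein_coding", "lincRNA"),
      stringsAsFactors = FALSE)
    gid <- gid + k
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               biotype = character(0))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)

  list(genome = seqs, chrom_sizes = chrom_sizes, genes = genes)
}

## internal: simple repeats placed clear of planted sites, so that no
## planted peak is repeat-dominated (the repeat filter must not erase the
## recoverable truth)
.sim_repeats <- function(cfg, chrom_names, site_gr) {
  ch <- character(0); s <- integer(0); w <- integer(0)
  site_ch <- as.character(GenomeInfoDb::seqnames(site_gr))
  site_s <- BiocGenerics::start(site_gr)
  site_e <- BiocGenerics::end(site_gr)
  tries <- 0L
  while (length(ch) < cfg$n_repeats && tries < 50L * cfg$n_repeats) {
    tries <- tries + 1L
    wi <- sample(50:500, 1)
    ci <- sample(chrom_names, 1)
    si <- sample.int(cfg$chrom_length - wi, 1)
    clash <- site_ch == ci & site_s <= si + wi - 1L & site_e >= si
    if (!any(clash)) {
      ch <- c(ch, ci); s <- c(s, si); w <- c(w, wi)
    }
  }
  BiocGenerics::sort(GenomicRanges::GRanges(
    factor(ch, levels = chrom_names), IRanges::IRanges(s, width = w)))
}

## internal: choose planted sites for one track
.sim_sites <- function(cfg, track, n, tss_frac, shared_frac, genes,
                       taken_summits, chrom_sizes) {
  chrom_names <- names(chrom_sizes)
  n_tss <- round(tss_frac * n)
  n_tss <- min(n_tss, nrow(genes))
  width <- pmax(100L, as.integer(round(
    rnorm(n, cfg$peak_width_mean, 0.15 * cfg$peak_width_mean))))
  chrom <- character(n); summit <- integer(n)
  tss_gene <- rep(NA_character_, n)
  margin <- 2500L
  if (n_tss > 0) {
    gi <- sample.int(nrow(genes), n_tss)
    off <- pmax(-240L, pmin(240L, as.integer(round(rnorm(n_tss, 0, 80)))))
    chrom[seq_len(n_tss)] <- genes$chrom[gi]
    summit[seq_len(n_tss)] <- pmin(pmax(genes$tss[gi] + off, margin),
                                   cfg$chrom_length - margin)
    tss_gene[seq_len(n_tss)] <- genes$gene_id[gi]
  }
  # non-TSS sites: keep clear of every TSS and of same-track sites
  placed <- data.frame(chrom = chrom[seq_len(n_tss)],
                       summit = summit[seq_len(n_tss)])
  for (j in seq_len(n - n_tss)) {
    i <- n_tss + j
    repeat {
      ch <- sample(chrom_names, 1)
      s <- sample(margin:(cfg$chrom_length - margin), 1)
      tss_clear <- !any(genes$chrom == ch & abs(genes$tss - s) < 2500)
      own <- c(placed$summit[placed$chrom == ch],
               taken_summits$summit[taken_summits$chrom == ch])
      site_clear <- !length(own) || all(abs(own - s) >= 1500)
      if (tss_clear && site_clear) break
    }
    chrom[i] <- ch; summit[i] <- s
    placed <- rbind(placed, data.frame(chrom = ch, summit = s))
  }
  presence <- ifelse(runif(n) < shared_frac, "both",
                     ifelse(runif(n) < 0.5, "control_only", "patient_only"))
  data.frame(mark = track, chrom = chrom, summit = summit, width = width,
             start = pmax(1L, summit - width %/% 2L),
             end = summit + width %/% 2L,
             tss_gene = tss_gene, presence = presence,
             stringsAsFactors = FALSE)
}

#' Simulate the full synthetic study
#'
#' Generates the genome (with planted E-box motifs), gene annotation,
#' simple repeats, planted peak sites with per-sample multipliers and
#' differential effects, reads for every sample x track plus input
#' chromatin, variant/GWAS/LD tables and a qPCR table — all under one seed,
#' with every planted object recorded in truth tables.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study`: `config`, `genome`
#'   (`DNAStringSet`), `chrom_sizes`, `genes`, `repeats`, `sites` (truth
#'   table of planted peaks), `reads` (nested list `[[sample]][[track]]`),
#'   `input_reads`, `variants`, `dbsnp129`, `dbsnp132`, `gwas`, `ld`,
#'   `qpcr`, `variant_truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  gen <- .sim_genome(cfg)

  # ---- planted sites ----
  tracks <- c(cfg$marks, cfg$tf)
  taken <- data.frame(chrom = character(0), summit = integer(0))
  sites <- list()
  for (tr in tracks) {
    is_tf <- tr == cfg$tf
    s <- .sim_sites(cfg, tr,
                    n = if (is_tf) cfg$n_peaks_tf else cfg$n_peaks_hm,
                    tss_frac = if (is_tf) cfg$tf_tss_fraction
                               else cfg$tss_fraction[[tr]],
                    shared_frac = if (is_tf) cfg$shared_fraction_tf
                                  else cfg$shared_fraction,
                    genes = gen$genes, taken_summits = taken,
                    chrom_sizes = gen$chrom_sizes)
    taken <- rbind(taken, s[, c("chrom", "summit")])
    sites[[tr]] <- s
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  n_sites <- nrow(sites)
  sites$site_id <- sprintf("site_%03d", seq_len(n_sites))
  sites$artifact <- FALSE

  # per-sample multipliers: shared base with mild per-sample noise
  base <- cfg$peak_read_multiplier * exp(rnorm(n_sites, 0, cfg$site_height_sd))
  mc <- base * exp(rnorm(n_sites, 0, cfg$sample_noise_sd))
  mp <- base * exp(rnorm(n_sites, 0, cfg$sample_noise_sd))
  mc[sites$presence == "patient_only"] <- 0
  mp[sites$presence == "control_only"] <- 0

  # differential effects among shared histone sites
  sites$direction <- ifelse(sites$presence == "patient_only",
                            "higher_in_patient",
                            ifelse(sites$presence == "control_only",
                                   "higher_in_control", "none"))
  # at differential sites the fold is the designated asymmetry: both
  # samples share the site height and the favored one is scaled by exactly
  # differential_fold (per-sample height noise applies only elsewhere)
  for (mk in cfg$marks) {
    shared <- which(sites$mark == mk & sites$presence == "both")
    n_diff <- 2L * (round(cfg$differential_fraction * length(shared)) %/% 2L)
    if (n_diff > 0) {
      pick <- sample(shared, n_diff)
      up <- pick[seq_len(n_diff / 2)]
      dn <- pick[-seq_len(n_diff / 2)]
      mc[up] <- base[up]
      mp[up] <- base[up] * cfg$differential_fold
      mc[dn] <- base[dn] * cfg$differential_fold
      mp[dn] <- base[dn]
      sites$direction[up] <- "higher_in_patient"
      sites$direction[dn] <- "higher_in_control"
    }
  }
  sites$mult_control <- mc
  sites$mult_patient <- mp

  # input-artifact regions: enriched in input and in both TF ChIPs
  if (cfg$n_input_artifacts > 0) {
    art <- .sim_sites(cfg, cfg$tf, cfg$n_input_artifacts, tss_frac = 0,
                      shared_frac = 1, genes = gen$genes,
                      taken_summits = taken, chrom_sizes = gen$chrom_sizes)
    art$site_id <- sprintf("artifact_%02d", seq_len(nrow(art)))
    art$artifact <- TRUE
    art$direction <- "none"
    art$mult_control <- art$mult_patient <- cfg$peak_read_multiplier
    sites <- rbind(sites, art)
  }

  # ---- plant E-box motifs near TF summits ----
  sites$motif <- NA_character_
  sites$motif_start <- NA_integer_
  tf_idx <- which(sites$mark == cfg$tf & !sites$artifact)
  n_motif <- round(cfg$motif_fraction * length(tf_idx))
  if (n_motif > 0) {
    chosen <- sample(tf_idx, n_motif)
    sites$motif[chosen] <- sample(c("CACGTG", "CACATG"), n_motif,
                                  replace = TRUE)
    sites$motif_start[chosen] <- sites$summit[chosen] +
      sample(-45:40, n_motif, replace = TRUE)
    for (i in chosen) {
      at <- IRanges::IRanges(sites$motif_start[i], width = 6L)
      gen$genome[[sites$chrom[i]]] <- Biostrings::replaceAt(
        gen$genome[[sites$chrom[i]]], at, sites$motif[i])
    }
  }

  # ---- simple repeats (clear of planted sites) ----
  pad <- cfg$fragment_length
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(pmax(1L, sites$start - pad),
                                  sites$end + pad))
  gen$repeats <- .sim_repeats(cfg, names(gen$chrom_sizes), site_gr)

  # ---- reads ----
  samples <- c("control", "patient")
  reads <- lapply(samples, function(smp) {
    out <- lapply(tracks, function(tr) {
      art_in_chip <- sites$artifact & tr == cfg$tf
      df <- if (tr == cfg$tf) cfg$tf_depth_factor else cfg$depth_factor
      .sim_track_reads(cfg, gen$chrom_sizes,
                       sites[sites$mark == tr | art_in_chip, , drop = FALSE],
                       mult_col = paste0("mult_", smp),
                       depth = df[[smp]])
    })
    names(out) <- tracks
    out
  })
  names(reads) <- samples
  art_sites <- sites[sites$artifact, , drop = FALSE]
  art_sites$mult_input <- rep(cfg$peak_read_multiplier, nrow(art_sites))
  input_reads <- .sim_track_reads(cfg, gen$chrom_sizes, art_sites,
                                  mult_col = "mult_input", depth = 1.0)

  # ---- variants & annotation tables ----
  vr <- .sim_variants(cfg, gen, sites)

  # ---- qPCR table ----
  qpcr <- .sim_qpcr(cfg, sites)

  structure(c(list(config = cfg), gen,
              list(sites = sites, reads = reads, input_reads = input_reads),
              vr, list(qpcr = qpcr)),
            class = "sim_study")
}

## internal: reads for one track of one sample. Fragments at planted sites
## are positioned to contain the planted summit (as ChIP fragments contain
## the bound site); read-start counts follow Poisson rates.
.sim_track_reads <- function(cfg, chrom_sizes, sites, mult_col, depth) {
  L <- cfg$fragment_length
  rl <- cfg$read_length
  chrom_names <- names(chrom_sizes)
  total_len <- sum(as.numeric(chrom_sizes))
  n_bg <- rpois(1, cfg$background_rate * total_len * depth)
  bg_chrom <- sample(chrom_names, n_bg, replace = TRUE,
                     prob = as.numeric(chrom_sizes))
  bg_start <- vapply(chrom_sizes[bg_chrom] - rl + 1L,
                     function(m) sample.int(m, 1), integer(1))
  chroms <- bg_chrom
  starts <- bg_start
  strands <- sample(c("+", "-"), n_bg, replace = TRUE)
  base_rate <- if (is.null(cfg$peak_base_rate)) cfg$background_rate
               else cfg$peak_base_rate
  for (i in seq_len(nrow(sites))) {
    m <- sites[[mult_col]][i]
    if (is.na(m) || m <= 1) next
    lam <- (m - 1) * base_rate * sites$width[i] * depth
    k <- rpois(1, lam)
    if (k == 0) next
    str <- sample(c("+", "-"), k, replace = TRUE)
    sm <- sites$summit[i]
    st <- integer(k)
    plus <- str == "+"
    # + read: fragment [u, u+L) covers the summit
    st[plus] <- sm - sample.int(L, sum(plus), replace = TRUE) + 1L
    # - read: fragment end v in [summit, summit+L); read is its 3'-most rl bp
    v <- sm + sample.int(L, sum(!plus), replace = TRUE) - 1L
    st[!plus] <- v - rl + 1L
    chroms <- c(chroms, rep(sites$chrom[i], k))
    starts <- c(starts, st)
    strands <- c(strands, str)
  }
  starts <- pmax(1L, pmin(starts, chrom_sizes[chroms] - rl + 1L))
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, width = rl),
                               strand = strands)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$total_mapped <- length(gr)
  gr
}

## internal: variants with recorded truth classes
.sim_variants <- function(cfg, gen, sites) {
  n <- cfg$n_variants
  hm <- sites[sites$mark %in% cfg$marks, , drop = FALSE]
  hm_gr <- GenomicRanges::GRanges(hm$chrom, IRanges::IRanges(hm$start, hm$end))
  diff_gr <- hm_gr[hm$direction != "none"]
  ctrl_gr <- hm_gr[hm$presence %in% c("both", "control_only")]
  pat_gr <- hm_gr[hm$presence %in% c("both", "patient_only")]

  chrom <- character(n); pos <- integer(n)
  in_peak_target <- runif(n) < 0.6
  for (i in seq_len(n)) {
    if (in_peak_target[i] && length(hm_gr)) {
      j <- sample.int(length(hm_gr), 1)
      chrom[i] <- hm$chrom[j]
      pos[i] <- sample(hm$start[j]:hm$end[j], 1)
    } else {
      repeat {
        ch <- sample(names(gen$chrom_sizes), 1)
        p <- sample.int(cfg$chrom_length, 1)
        probe <- GenomicRanges::GRanges(ch, IRanges::IRanges(p, width = 1L))
        if (!any(IRanges::overlapsAny(probe, hm_gr))) break
      }
      chrom[i] <- ch; pos[i] <- p
    }
  }
  ref <- fetch_sequence(gen$genome,
                        GenomicRanges::GRanges(chrom,
                                               IRanges::IRanges(pos, width = 1L)))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)

  depth_class <- sample(c("high", "low", "mid"), n, replace = TRUE,
                        prob = c(0.10, 0.15, 0.75))
  depth <- integer(n)
  depth[depth_class == "high"] <- sample(101:250, sum(depth_class == "high"),
                                         replace = TRUE)
  depth[depth_class == "low"] <- sample(1:9, sum(depth_class == "low"),
                                        replace = TRUE)
  depth[depth_class == "mid"] <- sample(10:100, sum(depth_class == "mid"),
                                        replace = TRUE)
  lowq <- runif(n) < 0.15
  quality <- ifelse(lowq, round(runif(n, 10, 49.9), 1),
                    round(runif(n, 50, 300), 1))

  u <- runif(n)
  known129 <- u < cfg$known129_fraction
  known132 <- u < cfg$known129_fraction + cfg$known132_only_fraction

  variants <- data.frame(
    sample_id = sample(c("control", "patient"), n, replace = TRUE,
                       prob = c(0.35, 0.65)),
    chrom = chrom, pos = pos, id = sprintf("snp_%04d", seq_len(n)),
    ref = ref, alt = alt, quality = quality, depth = depth,
    stringsAsFactors = FALSE)

  pos_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  truth <- variants
  truth$known129 <- known129
  truth$known132 <- known132
  truth$pass_depth <- depth <= 100
  truth$pass_quality <- quality >= 50
  truth$in_diff_region <- IRanges::overlapsAny(pos_gr, diff_gr)
  truth$novelty <- ifelse(known129, "known",
                          ifelse(known132, "dropped_132", "novel"))
  truth$novel_in_peak <- truth$pass_depth & truth$pass_quality &
    truth$novelty == "novel" & truth$in_diff_region & depth >= 10
  in_c <- IRanges::overlapsAny(pos_gr, ctrl_gr)
  in_p <- IRanges::overlapsAny(pos_gr, pat_gr)
  truth$hm_overlap <- ifelse(in_c & in_p, "both",
                             ifelse(in_c, "control_only",
                                    ifelse(in_p, "patient_only", "none")))

  # GWAS catalogue: planted matches + decoy-only entries
  kw_traits <- c("Type 2 diabetes", "Fasting plasma glucose",
                 "Chronic hepatitis B", "Hepatocellular carcinoma",
                 "Insulin resistance", "LDL cholesterol levels",
                 "Lipid metabolism phenotypes", "Liver enzyme levels",
                 "Obesity-related traits", "Triglycerides")
  other_traits <- c("Height", "Educational attainment", "Eye color",
                    "Coronary artery disease", "Asthma")
  n_gwas <- round(cfg$gwas_fraction * n)
  gi <- sample.int(n, n_gwas)
  is_kw <- runif(n_gwas) < cfg$gwas_keyword_fraction
  gwas <- data.frame(
    snp_id = variants$id[gi], chrom = chrom[gi], pos = pos[gi],
    trait = ifelse(is_kw, sample(kw_traits, n_gwas, replace = TRUE),
                   sample(other_traits, n_gwas, replace = TRUE)),
    stringsAsFactors = FALSE)
  n_decoy <- 20L
  decoy <- data.frame(
    snp_id = sprintf("rs_cat_%03d", seq_len(n_decoy)),
    chrom = sample(names(gen$chrom_sizes), n_decoy, replace = TRUE),
    pos = sample.int(cfg$chrom_length, n_decoy),
    trait = sample(c(kw_traits, other_traits), n_decoy, replace = TRUE),
    stringsAsFactors = FALSE)
  gwas <- rbind(gwas, decoy)
  truth$gwas_keyword <- rep(NA_character_, n)
  kw_list <- gwas_keywords()
  matched_kw <- vapply(tolower(gwas$trait), function(tr) {
    h <- kw_list[vapply(kw_list, grepl, logical(1), x = tr, fixed = TRUE)]
    if (length(h)) h[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  mi <- match(variants$id, gwas$snp_id)
  truth$gwas_keyword <- matched_kw[mi]

  # LD table: planted proxies to keyword-matching catalogue SNPs,
  # plus edges that fail the r2 or distance bound, plus decoy-decoy noise
  kw_cat <- gwas$snp_id[!is.na(matched_kw)]
  non_cat <- which(is.na(mi))
  n_ld <- min(length(non_cat), round(cfg$ld_fraction * n))
  ld <- NULL
  truth$ld_proxy_of <- rep(NA_character_, n)
  if (n_ld > 0 && length(kw_cat)) {
    li <- sample(non_cat, n_ld)
    partner <- sample(kw_cat, n_ld, replace = TRUE)
    r2 <- round(runif(n_ld, 0.4, 1), 3)
    dist <- sample.int(round(1.6 * cfg$ld_block_size), n_ld)
    ld <- data.frame(snp_a = variants$id[li], snp_b = partner,
                     r2 = r2, distance = dist, stringsAsFactors = FALSE)
    is_proxy <- r2 >= 0.8 & dist <= 500000
    truth$ld_proxy_of[li[is_proxy]] <- partner[is_proxy]
  }
  noise <- data.frame(
    snp_a = sample(decoy$snp_id, 10, replace = TRUE),
    snp_b = sample(sprintf("rs_x_%03d", 1:50), 10, replace = TRUE),
    r2 = round(runif(10, 0.1, 1), 3),
    distance = sample.int(1e6, 10), stringsAsFactors = FALSE)
  ld <- rbind(ld, noise)
  swap <- ld$snp_a > ld$snp_b
  tmp <- ld$snp_a[swap]; ld$snp_a[swap] <- ld$snp_b[swap]; ld$snp_b[swap] <- tmp
  ld <- ld[!duplicated(ld[, c("snp_a", "snp_b")]), , drop = FALSE]
  rownames(ld) <- NULL

  list(variants = variants,
       dbsnp129 = variants$id[known129],
       dbsnp132 = variants$id[known132],
       gwas = gwas, ld = ld, variant_truth = truth)
}

## internal: qPCR validation table (positives at planted TF sites,
## negatives at background regions)
.sim_qpcr <- function(cfg, sites) {
  tf_both <- sites[sites$mark == cfg$tf & !sites$artifact &
                     sites$presence == "both", , drop = FALSE]
  n_pos <- min(cfg$n_qpcr_pos, nrow(tf_both))
  pick <- tf_both[sample.int(nrow(tf_both), n_pos), , drop = FALSE]
  rows <- list()
  for (smp in c("control", "patient")) {
    mult <- pick[[paste0("mult_", smp)]]
    pos_val <- 0.4 * mult * exp(rnorm(n_pos, 0, 0.35))
    neg_val <- abs(rnorm(cfg$n_qpcr_neg, 1, 0.2))
    rows[[smp]] <- data.frame(
      region_id = c(pick$site_id, sprintf("neg_%02d", seq_len(cfg$n_qpcr_neg))),
      chrom = c(pick$chrom, rep(NA_character_, cfg$n_qpcr_neg)),
      summit = c(pick$summit, rep(NA_integer_, cfg$n_qpcr_neg)),
      value = c(pos_val, neg_val),
      is_negative = rep(c(FALSE, TRUE), c(n_pos, cfg$n_qpcr_neg)),
      sample_id = smp, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected read count for one simulated track (closed form)
#'
#' Mean of the Poisson total-read-count distribution for a sample/track,
#' used to check the generator against its own configuration.
#'
#' @param sim A `sim_study`.
#' @param sample_id `"control"` or `"patient"`.
#' @param track Mark or TF name.
#' @return List with `mean` and `sd` of the total read count.
#' @export
expected_read_count <- function(sim, sample_id, track) {
  cfg <- sim$config
  depth <- if (track == cfg$tf) cfg$tf_depth_factor[[sample_id]]
           else cfg$depth_factor[[sample_id]]
  total_len <- sum(as.numeric(sim$chrom_sizes))
  s <- sim$sites[sim$sites$mark == track |
                   (sim$sites$artifact & track == cfg$tf), , drop = FALSE]
  m <- s[[paste0("mult_", sample_id)]]
  base_rate <- if (is.null(cfg$peak_base_rate)) cfg$background_rate
               else cfg$peak_base_rate
  lam <- cfg$background_rate * total_len * depth +
    sum(pmax(0, m - 1) * base_rate * s$width * depth)
  list(mean = lam, sd = sqrt(lam))
}

#' Write a simulated study to disk
#'
#' Writes FASTA, gene/repeat annotation, per-track read BEDs, input reads,
#' per-sample VCFs, catalogue ID lists, GWAS/LD/qPCR tables and the truth
#' tables into `outdir`.
#'
#' @param sim A `sim_study` from [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  paths <- c(genome = p("genome.fa"), genes = p("genes.tsv"),
             repeats = p("repeats.bed"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_tsv_table(sim$genes[, c("gene_id", "chrom", "strand", "start",
                                "end", "biotype")], paths["genes"])
  write_intervals(sim$repeats, paths["repeats"], "bed")
  for (smp in names(sim$reads)) {
    for (tr in names(sim$reads[[smp]])) {
      f <- p(sprintf("reads_%s_%s.bed", smp, tr))
      write_intervals(sim$reads[[smp]][[tr]], f, "bed")
      paths[paste0("reads_", smp, "_", tr)] <- f
    }
  }
  write_intervals(sim$input_reads, p("reads_input.bed"), "bed")
  paths["input"] <- p("reads_input.bed")
  for (smp in c("control", "patient")) {
    v <- sim$variants[sim$variants$sample_id == smp, , drop = FALSE]
    f <- p(sprintf("variants_%s.vcf", smp))
    write_vcf(v, f, sample_id = smp)
    paths[paste0("variants_", smp)] <- f
  }
  writeLines(sim$dbsnp129, p("dbsnp129.txt"))
  writeLines(sim$dbsnp132, p("dbsnp132.txt"))
  write_tsv_table(sim$gwas, p("gwas_catalogue.tsv"))
  write_tsv_table(sim$ld, p("ld_table.tsv"))
  write_tsv_table(sim$qpcr, p("qpcr.tsv"))
  write_tsv_table(sim$sites, p("truth_sites.tsv"))
  write_tsv_table(sim$variant_truth, p("truth_variants.tsv"))
  paths <- c(paths, dbsnp129 = p("dbsnp129.txt"), dbsnp132 = p("dbsnp132.txt"),
             gwas = p("gwas_catalogue.tsv"), ld = p("ld_table.tsv"),
             qpcr = p("qpcr.tsv"), truth_sites = p("truth_sites.tsv"),
             truth_variants = p("truth_variants.tsv"))
  invisible(paths)
}
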