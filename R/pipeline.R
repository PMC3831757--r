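## End-to-end orchestration over a simulated (or user-supplied) study:
## peak calling -> top-N capping -> motif annotation -> differential
## regions -> footprints -> genomic classification -> variant cascade ->
## qPCR calls, with per-stage row counts collected into a manifest.

#' Run the full analysis over a synthetic study
#'
#' Simulates a study (or accepts one), calls TF peaks in both samples with
#' the fragment-extension caller (input-filtered, motif-annotated), calls
#' histone-mark peaks, caps peak lists at a common top-N, builds union
#' differential regions with RPM counts and direction ranking, assigns
#' nearest genes, classifies genomic distribution, computes TSS footprints
#' with joint normalization, runs the variant cascade, and applies the
#' qPCR enrichment call.
#'
#' @param sim_cfg A [sim_config()]; ignored when `sim` is given.
#' @param sim Optionally a pre-built `sim_study`.
#' @param peak_cfg_control,peak_cfg_patient [peakcall_config()]s; the
#'   defaults use pileup thresholds 10 (control) and 5 (patient), the
#'   thresholds chosen in the emulated study to balance its unequal library
#'   depths.
#' @param diff_cfg A [differential_config()]; `n_top` defaults to the
#'   planted per-direction differential count so that ranked lists are
#'   interpretable at synthetic scale.
#' @param var_cfg A [variant_filter_config()].
#' @param round_to Top-N rounding unit for [select_top_peaks()]; default
#'   scales to the synthetic peak counts (10 at synthetic scale, 1000 at
#'   study scale).
#' @param outdir Optional directory: when given, all result tables and a
#'   JSON manifest are written there.
#' @return A list of class `chromdiff_run` with elements `sim`,
#'   `tf_peaks`, `hm_peaks`, `differential`, `genomic_distribution`,
#'   `footprints`, `presence`, `agreement`, `variants`, `qpcr`,
#'   `manifest`.
#' @export
run_pipeline <- function(sim_cfg = sim_config(), sim = NULL,
                         peak_cfg_control = peakcall_config(min_height = 10),
                         peak_cfg_patient = peakcall_config(min_height = 5),
                         diff_cfg = NULL, var_cfg = variant_filter_config(),
                         round_to = 10L, outdir = NULL) {
  if (is.null(sim)) sim <- simulate_study(sim_cfg)
  cfg <- sim$config
  peak_cfgs <- list(control = peak_cfg_control, patient = peak_cfg_patient)
  counts <- list()

  # ---- TF peaks: dedup, extend, pileup, call, input-filter, motif ----
  input_cov <- extend_and_pileup(
    deduplicate_reads(sim$input_reads), peak_cfg_control, sim$chrom_sizes)
  tf_peaks <- list()
  for (smp in c("control", "patient")) {
    reads <- sim$reads[[smp]][[cfg$tf]]
    total <- S4Vectors::metadata(reads)$total_mapped
    cov <- extend_and_pileup(deduplicate_reads(reads), peak_cfgs[[smp]],
                             sim$chrom_sizes)
    pk <- call_peaks(cov, peak_cfgs[[smp]], total_mapped = total,
                     sample_id = smp, mark = cfg$tf)
    pk <- suppressMessages(filter_by_input(pk, input_cov, peak_cfgs[[smp]]))
    pk <- scan_ebox(pk, sim$genome, peak_cfgs[[smp]])
    tf_peaks[[smp]] <- pk
    counts[[paste0("tf_peaks_", smp)]] <- length(pk)
  }

  # ---- histone-mark peaks per sample ----
  hm_peaks <- list()
  for (mk in cfg$marks) {
    per_sample <- list()
    for (smp in c("control", "patient")) {
      reads <- sim$reads[[smp]][[mk]]
      total <- S4Vectors::metadata(reads)$total_mapped
      cov <- extend_and_pileup(deduplicate_reads(reads), peak_cfgs[[smp]],
                               sim$chrom_sizes)
      per_sample[[smp]] <- call_peaks(cov, peak_cfgs[[smp]],
                                      total_mapped = total,
                                      sample_id = smp, mark = mk)
    }
    per_sample <- select_top_peaks(per_sample, round_to = round_to)
    hm_peaks[[mk]] <- per_sample
    counts[[paste0("hm_peaks_", mk)]] <- length(per_sample$control)
  }

  # ---- differential regions per mark ----
  if (is.null(diff_cfg)) {
    # n_top scaled to the planted per-direction region count
    tab <- table(sim$sites$mark[sim$sites$direction != "none"],
                 sim$sites$direction[sim$sites$direction != "none"])
    diff_cfg <- differential_config(n_top = max(1L, tab))
  }
  differential <- list()
  for (mk in cfg$marks) {
    regions <- merge_peak_regions(hm_peaks[[mk]]$control,
                                  hm_peaks[[mk]]$patient)
    regions <- filter_simple_repeats(regions, sim$repeats, diff_cfg)
    rc <- sim$reads$control[[mk]]
    rp <- sim$reads$patient[[mk]]
    regions$rpm_control <- count_rpm(regions, rc)
    regions$rpm_patient <- count_rpm(regions, rp)
    ranked <- rank_differential(regions, diff_cfg)
    for (dir in names(ranked)) {
      ann <- nearest_tss(ranked[[dir]], sim$genes)
      S4Vectors::mcols(ranked[[dir]]) <- cbind(
        S4Vectors::mcols(ranked[[dir]]), ann)
    }
    differential[[mk]] <- ranked
    counts[[paste0("diff_regions_", mk)]] <- length(regions)
  }
  gdist <- genomic_distribution(differential, sim$genes, diff_cfg)

  # ---- TSS footprints ----
  footprints <- lapply(cfg$marks, function(mk) {
    tss_footprint(sim$reads$patient[[mk]], sim$genes, diff_cfg, mark = mk)
  })
  footprints <- normalize_footprints(footprints)
  names(footprints) <- cfg$marks

  # ---- gene presence and TF agreement ----
  presence <- lapply(hm_peaks, function(ps)
    peak_gene_presence(ps$control, ps$patient, sim$genes, diff_cfg))
  agreement <- tss_peak_agreement(tf_peaks$patient, tf_peaks$control,
                                  sim$genes, diff_cfg)

  # ---- variant cascade (per sample, against differential regions) ----
  diff_all <- GenomicRanges::reduce(unlist(GenomicRanges::GRangesList(
    lapply(differential, function(d)
      c(GenomicRanges::granges(d[[1]]), GenomicRanges::granges(d[[2]]))))))
  pooled <- function(smp) GenomicRanges::reduce(
    unlist(GenomicRanges::GRangesList(lapply(hm_peaks, `[[`, smp))))
  variants <- list()
  for (smp in c("control", "patient")) {
    v <- sim$variants[sim$variants$sample_id == smp, , drop = FALSE]
    variants[[smp]] <- annotate_variants(
      v, sim$dbsnp129, sim$dbsnp132, diff_all, sim$gwas, sim$ld,
      pooled("control"), pooled("patient"), var_cfg)
    counts[[paste0("variants_known_", smp)]] <- nrow(variants[[smp]]$known)
    counts[[paste0("variants_novel_in_peaks_", smp)]] <-
      nrow(variants[[smp]]$novel_in_peaks)
  }

  # ---- qPCR calls ----
  qpcr <- list()
  for (smp in c("control", "patient")) {
    q <- sim$qpcr[sim$qpcr$sample_id == smp, , drop = FALSE]
    bg <- qpcr_background(q)
    q$call <- qpcr_call(q$value, bg)
    pos <- q[!q$is_negative, , drop = FALSE]
    pk <- tf_peaks[[smp]]
    h <- vapply(seq_len(nrow(pos)), function(i) {
      same <- which(as.character(GenomeInfoDb::seqnames(pk)) == pos$chrom[i])
      if (!length(same)) return(NA_real_)
      d <- abs(pk$summit[same] - pos$summit[i])
      if (min(d) <= 500) pk$height_rpm[same[which.min(d)]] else NA_real_
    }, numeric(1))
    ok <- !is.na(h)
    qpcr[[smp]] <- list(table = q, background = bg,
                        r2 = if (sum(ok) >= 3) agreement_r2(h[ok], pos$value[ok])
                             else NA_real_)
    counts[[paste0("qpcr_positive_", smp)]] <- sum(q$call == "positive")
  }

  manifest <- list(package = "chromdiff",
                   version = as.character(packageVersion("chromdiff")),
                   seed = cfg$seed, counts = counts)
  run <- structure(list(sim = sim, tf_peaks = tf_peaks, hm_peaks = hm_peaks,
                        differential = differential,
                        genomic_distribution = gdist,
                        footprints = footprints, presence = presence,
                        agreement = agreement, variants = variants,
                        qpcr = qpcr, manifest = manifest),
                   class = "chromdiff_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' Write pipeline outputs and manifest
#'
#' @param run A `chromdiff_run`.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  for (smp in names(run$tf_peaks)) {
    write_intervals(run$tf_peaks[[smp]], p(sprintf("tf_peaks_%s.narrowPeak",
                                                   smp)), "narrowPeak")
  }
  for (mk in names(run$differential)) {
    for (dir in names(run$differential[[mk]])) {
      gr <- run$differential[[mk]][[dir]]
      df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                       start = BiocGenerics::start(gr),
                       end = BiocGenerics::end(gr),
                       as.data.frame(S4Vectors::mcols(gr)))
      write_tsv_table(df, p(sprintf("differential_%s_%s.tsv", mk, dir)))
    }
  }
  write_tsv_table(run$genomic_distribution, p("genomic_distribution.tsv"))
  write_tsv_table(footprint_table(run$footprints), p("footprints.tsv"))
  for (smp in names(run$variants)) {
    write_tsv_table(run$variants[[smp]]$novel_in_peaks,
                    p(sprintf("novel_variants_%s.tsv", smp)))
    write_tsv_table(run$variants[[smp]]$known,
                    p(sprintf("known_variants_%s.tsv", smp)))
  }
  for (smp in names(run$qpcr)) {
    write_tsv_table(run$qpcr[[smp]]$table, p(sprintf("qpcr_calls_%s.tsv", smp)))
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.chromdiff_run <- function(x, ...) {
  cat("<chromdiff_run> seed", x$manifest$seed, "\n")
  for (nm in names(x$manifest$counts)) {
    cat(sprintf("  %-32s %s\n", nm, x$manifest$counts[[nm]]))
  }
  invisible(x)
}
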