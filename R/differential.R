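## Differential histone-modification analysis: union peak regions, RPM
## counting, difference ranking, nearest-TSS gene assignment, genomic
## classification, and simple-repeat filtering.

#' Differential-analysis configuration
#'
#' @param n_top Regions kept per direction (default 1000).
#' @param tss_window Half-width in bp of the TSS-proximal window (default
#'   2000, i.e. +/- 2 kb of a TSS).
#' @param footprint_halfwidth Half-width of the TSS footprint (default 1000,
#'   giving 2001 positions).
#' @param repeat_overlap_max Maximum tolerated fraction of a region covered
#'   by simple repeats (default 0.8, strict: regions above are removed).
#' @param tss_corr_dist Peaks within this distance of a TSS enter the
#'   height-correlation comparison (default 250 bp).
#' @param peak_match_dist Two summits within this distance are "the same
#'   site" for cross-sample agreement (default 100 bp).
#' @return A list of class `differential_config`.
#' @export
differential_config <- function(n_top = 1000L, tss_window = 2000L,
                                footprint_halfwidth = 1000L,
                                repeat_overlap_max = 0.8,
                                tss_corr_dist = 250L, peak_match_dist = 100L) {
  stopifnot(n_top > 0, tss_window > 0, footprint_halfwidth > 0,
            repeat_overlap_max > 0, repeat_overlap_max <= 1,
            tss_corr_dist > 0, peak_match_dist > 0)
  structure(list(n_top = as.integer(n_top),
                 tss_window = as.integer(tss_window),
                 footprint_halfwidth = as.integer(footprint_halfwidth),
                 repeat_overlap_max = repeat_overlap_max,
                 tss_corr_dist = as.integer(tss_corr_dist),
                 peak_match_dist = as.integer(peak_match_dist)),
            class = "differential_config")
}

#' Union-merge the peak regions of two samples
#'
#' Regions identified in either sample are merged (overlapping or book-ended
#' intervals collapse to one region) so no genomic position is counted
#' twice. Each output region records which sample(s) contributed.
#'
#' @param peaks_control,peaks_patient `GRanges` of the same mark.
#' @return `GRanges` with a `source` column in
#'   `{control, patient, both}`.
#' @export
merge_peak_regions <- function(peaks_control, peaks_patient) {
  merged <- GenomicRanges::reduce(
    c(GenomicRanges::granges(peaks_control),
      GenomicRanges::granges(peaks_patient)), ignore.strand = TRUE)
  in_c <- IRanges::overlapsAny(merged, peaks_control, ignore.strand = TRUE)
  in_p <- IRanges::overlapsAny(merged, peaks_patient, ignore.strand = TRUE)
  merged$source <- ifelse(in_c & in_p, "both",
                          ifelse(in_c, "control", "patient"))
  merged
}

#' Reads-per-million counts over regions
#'
#' A read counts toward a region when its aligned interval overlaps the
#' region by at least one base; the count is normalized by the total number
#' of mapped reads in the library.
#'
#' @param regions `GRanges`.
#' @param reads `GRanges` of aligned reads.
#' @param total_mapped Library size; defaults to
#'   `metadata(reads)$total_mapped`, falling back to `length(reads)`.
#' @return Numeric vector of RPM values, one per region.
#' @export
count_rpm <- function(regions, reads, total_mapped = NULL) {
  if (is.null(total_mapped)) {
    total_mapped <- S4Vectors::metadata(reads)$total_mapped
    if (is.null(total_mapped)) total_mapped <- length(reads)
  }
  if (total_mapped <= 0) stop("total_mapped must be positive")
  n <- GenomicRanges::countOverlaps(regions, reads, ignore.strand = TRUE)
  n * 1e6 / total_mapped
}

#' Rank regions by enrichment difference, both directions
#'
#' Regions are ranked by `delta = rpm_patient - rpm_control`; the `n_top`
#' with the largest positive delta form the higher-in-patient list, the
#' `n_top` with the most negative delta the higher-in-control list. Ties
#' are broken by genomic order.
#'
#' @param regions `GRanges` with `rpm_control` and `rpm_patient` columns.
#' @param config A [differential_config()].
#' @return Named list of two `GRanges` (`higher_in_patient`,
#'   `higher_in_control`), each with `delta`, `direction`, `rank` columns.
#' @export
rank_differential <- function(regions, config = differential_config()) {
  stopifnot(!is.null(regions$rpm_control), !is.null(regions$rpm_patient))
  n_top <- min(config$n_top, length(regions))
  if (n_top < config$n_top) {
    warning("only ", length(regions), " regions available; n_top reduced")
  }
  regions$delta <- regions$rpm_patient - regions$rpm_control
  genomic <- order(as.character(GenomeInfoDb::seqnames(regions)),
                   BiocGenerics::start(regions))
  take <- function(decreasing, direction) {
    key <- if (decreasing) -regions$delta else regions$delta
    ord <- genomic[order(key[genomic])]   # stable: genomic order for ties
    out <- regions[ord[seq_len(n_top)]]
    out$direction <- direction
    out$rank <- seq_len(n_top)
    out
  }
  list(higher_in_patient = take(TRUE, "higher_in_patient"),
       higher_in_control = take(FALSE, "higher_in_control"))
}

#' Assign each region the gene with the closest TSS
#'
#' Distance is measured from the region's anchor (its `summit` column when
#' present, otherwise the midpoint) to the TSS, and reported signed in the
#' gene's reading direction: positive when the anchor lies downstream of the
#' TSS. Ties go to the lexicographically smaller `gene_id`.
#'
#' @param regions `GRanges`.
#' @param genes Gene table from [read_gene_table()].
#' @param biotype Optional biotype filter (e.g. `"protein_coding"`).
#' @return Data.frame with `nearest_gene` and signed `tss_distance` per
#'   region.
#' @export
nearest_tss <- function(regions, genes, biotype = NULL) {
  if (!is.null(biotype)) genes <- genes[genes$biotype %in% biotype, ]
  if (nrow(genes) == 0) stop("no genes pass the biotype filter")
  genes <- genes[order(genes$gene_id), ]
  anchor <- if (!is.null(regions$summit)) regions$summit
            else (BiocGenerics::start(regions) + BiocGenerics::end(regions)) %/% 2
  chroms <- as.character(GenomeInfoDb::seqnames(regions))
  gene_id <- character(length(regions))
  dist <- rep(NA_integer_, length(regions))
  for (ch in unique(chroms)) {
    ri <- which(chroms == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0) gi <- seq_len(nrow(genes))  # fall back genome-wide
    d <- abs(outer(anchor[ri], genes$tss[gi], "-"))
    best <- apply(d, 1, which.min)  # first (smallest gene_id) on ties
    g <- genes[gi[best], ]
    gene_id[ri] <- g$gene_id
    raw <- anchor[ri] - g$tss
    dist[ri] <- ifelse(g$strand == "+", raw, -raw)
  }
  data.frame(nearest_gene = gene_id, tss_distance = dist,
             stringsAsFactors = FALSE)
}

#' Classify regions by genomic context
#'
#' A region is `tss_proximal` when it overlaps the +/- `tss_window` interval
#' around any TSS (all biotypes), and `intragenic` when it overlaps any gene
#' body; otherwise `non_tss` / `intergenic`.
#'
#' @param regions `GRanges`.
#' @param genes Gene table from [read_gene_table()].
#' @param config A [differential_config()].
#' @return Data.frame with logical `tss_proximal` and `intragenic` columns.
#' @export
classify_regions <- function(regions, genes, config = differential_config()) {
  w <- config$tss_window
  tss_win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$tss - w), genes$tss + w))
  body <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmin(genes$tss, genes$tes), pmax(genes$tss, genes$tes)))
  data.frame(
    tss_proximal = IRanges::overlapsAny(regions, tss_win, ignore.strand = TRUE),
    intragenic = IRanges::overlapsAny(regions, body, ignore.strand = TRUE))
}

#' Tally differential regions into the six genomic-distribution categories
#'
#' Three marks times two directions, each split into TSS-proximal vs
#' non-TSS counts.
#'
#' @param ranked Named list: `ranked[[mark]][[direction]]` is a `GRanges`.
#' @param genes Gene table.
#' @param config A [differential_config()].
#' @return Data.frame with one row per (mark, direction) and columns
#'   `n_tss`, `n_non_tss`, `pct_tss`.
#' @export
genomic_distribution <- function(ranked, genes,
                                 config = differential_config()) {
  rows <- list()
  for (mark in names(ranked)) {
    for (dir in names(ranked[[mark]])) {
      cls <- classify_regions(ranked[[mark]][[dir]], genes, config)
      rows[[length(rows) + 1L]] <- data.frame(
        mark = mark, direction = dir,
        n_tss = sum(cls$tss_proximal),
        n_non_tss = sum(!cls$tss_proximal),
        pct_tss = 100 * mean(cls$tss_proximal))
    }
  }
  do.call(rbind, rows)
}

#' Remove regions dominated by simple repeats
#'
#' A region is removed when strictly more than `repeat_overlap_max` of its
#' bases are covered by the (union of the) repeat track; a region covered
#' exactly at the threshold is retained.
#'
#' @param regions `GRanges`.
#' @param repeats `GRanges` of the simpleRepeat track.
#' @param config A [differential_config()].
#' @return Retained regions, with `attr(, "n_removed")`.
#' @export
filter_simple_repeats <- function(regions, repeats,
                                  config = differential_config()) {
  if (length(regions) == 0) return(regions)
  rep_red <- GenomicRanges::reduce(GenomicRanges::granges(repeats),
                                   ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(regions, rep_red, ignore.strand = TRUE)
  covered <- numeric(length(regions))
  if (length(hits)) {
    ov <- IRanges::pintersect(regions[S4Vectors::queryHits(hits)],
                              rep_red[S4Vectors::subjectHits(hits)],
                              ignore.strand = TRUE)
    covered <- as.numeric(tapply(BiocGenerics::width(ov),
                                 S4Vectors::queryHits(hits), sum)[
                                   as.character(seq_along(regions))])
    covered[is.na(covered)] <- 0
  }
  frac <- covered / BiocGenerics::width(regions)
  keep <- frac <= config$repeat_overlap_max
  out <- regions[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Genes with peaks in both, one, or neither sample
#'
#' A gene "has" a peak in a sample when any peak of the mark overlaps the
#' +/- `tss_window` interval around its TSS.
#'
#' @param peaks_control,peaks_patient `GRanges` (one mark).
#' @param genes Gene table.
#' @param config A [differential_config()].
#' @return List with counts `both`, `control_only`, `patient_only`, `none`.
#' @export
peak_gene_presence <- function(peaks_control, peaks_patient, genes,
                               config = differential_config()) {
  w <- config$tss_window
  tss_win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$tss - w), genes$tss + w))
  in_c <- IRanges::overlapsAny(tss_win, peaks_control, ignore.strand = TRUE)
  in_p <- IRanges::overlapsAny(tss_win, peaks_patient, ignore.strand = TRUE)
  list(both = sum(in_c & in_p),
       control_only = sum(in_c & !in_p),
       patient_only = sum(!in_c & in_p),
       none = sum(!in_c & !in_p))
}

#' Cross-sample agreement of TSS-proximal peaks
#'
#' Peaks of set A whose summit lies within `tss_corr_dist` of a TSS are
#' matched to the nearest set-B summit within the same distance; the Pearson
#' correlation of matched heights is reported, together with the fraction of
#' all A peaks having a B summit within `peak_match_dist`.
#'
#' @param peaks_a,peaks_b `GRanges` with `summit` and `height` columns.
#' @param genes Gene table.
#' @param config A [differential_config()].
#' @return List with `r` (Pearson, `NA` when fewer than 3 matched pairs or
#'   degenerate variance), `n_pairs`, and `fraction_matched`.
#' @export
tss_peak_agreement <- function(peaks_a, peaks_b, genes,
                               config = differential_config()) {
  summit_gr <- function(p) GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(p), IRanges::IRanges(p$summit, width = 1L))
  sa <- summit_gr(peaks_a)
  sb <- summit_gr(peaks_b)
  frac <- if (length(sa) == 0) NA_real_ else {
    d_ab <- GenomicRanges::distanceToNearest(sa, sb, ignore.strand = TRUE)
    matched <- rep(FALSE, length(sa))
    matched[S4Vectors::queryHits(d_ab)] <-
      S4Vectors::mcols(d_ab)$distance <= config$peak_match_dist
    mean(matched)
  }
  tss <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$tss, width = 1L))
  near_tss <- function(s) {
    d <- GenomicRanges::distanceToNearest(s, tss, ignore.strand = TRUE)
    keep <- rep(FALSE, length(s))
    keep[S4Vectors::queryHits(d)] <-
      S4Vectors::mcols(d)$distance <= config$tss_corr_dist
    keep
  }
  ai <- which(near_tss(sa))
  r <- NA_real_
  n_pairs <- 0L
  if (length(ai) && length(sb)) {
    d <- GenomicRanges::distanceToNearest(sa[ai], sb, ignore.strand = TRUE)
    ok <- S4Vectors::mcols(d)$distance <= config$tss_corr_dist
    qa <- ai[S4Vectors::queryHits(d)[ok]]
    qb <- S4Vectors::subjectHits(d)[ok]
    n_pairs <- length(qa)
    if (n_pairs >= 3) {
      ha <- peaks_a$height[qa]
      hb <- peaks_b$height[qb]
      if (stats::sd(ha) > 0 && stats::sd(hb) > 0) r <- stats::cor(ha, hb)
    }
  }
  list(r = r, n_pairs = n_pairs, fraction_matched = frac)
}
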