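## Regulatory SNP filtering cascade and annotation.
##
## Stages: depth/quality filter -> known/novel split against two versioned
## variant catalogues -> restriction of novel sites to peak regions with
## adequate depth -> GWAS catalogue keyword overlap -> LD proxy expansion
## -> histone-peak overlap categorization. Every stage reports its removal
## counts so the cascade is conservation-auditable.

#' Default GWAS trait keywords
#'
#' Liver-, lipid- and glucose-metabolism related keywords used for the
#' case-insensitive substring match against catalogue trait strings.
#'
#' @return Lowercase character vector.
#' @export
gwas_keywords <- function() {
  c("diabetes", "fasting plasma glucose", "hepatitis",
    "hepatocellular carcinoma", "insulin", "ldl cholesterol",
    "lipid metabolism", "liver", "obesity", "triglycerides")
}

#' Variant-cascade configuration
#'
#' @param max_depth Sites with depth strictly above this are removed as
#'   likely repetitive (default 100).
#' @param min_quality Sites with quality strictly below this are removed
#'   (default 50).
#' @param min_peak_reads Minimum depth for a novel site inside a peak
#'   region (default 10, inclusive).
#' @param ld_r2_min Minimum r-squared for an LD proxy (default 0.8,
#'   inclusive).
#' @param ld_dist_max Maximum distance to the catalogue SNP in bp (default
#'   500000, inclusive).
#' @param keywords Lowercase GWAS trait keywords.
#' @return A list of class `variant_filter_config`.
#' @export
variant_filter_config <- function(max_depth = 100, min_quality = 50,
                                  min_peak_reads = 10, ld_r2_min = 0.8,
                                  ld_dist_max = 500000,
                                  keywords = gwas_keywords()) {
  stopifnot(max_depth > 0, min_quality > 0, min_peak_reads > 0,
            ld_r2_min > 0, ld_dist_max > 0, length(keywords) >= 1)
  structure(list(max_depth = max_depth, min_quality = min_quality,
                 min_peak_reads = min_peak_reads, ld_r2_min = ld_r2_min,
                 ld_dist_max = ld_dist_max, keywords = tolower(keywords)),
            class = "variant_filter_config")
}

#' Depth and quality filter
#'
#' Retains sites with `depth <= max_depth` and `quality >= min_quality`
#' (both boundaries retain). Records with missing depth or quality are
#' routed to a separate bucket, never silently kept.
#'
#' @param variants Data.frame from [read_variants()].
#' @param config A [variant_filter_config()].
#' @return List: `retained`, `removed_depth`, `removed_quality`,
#'   `missing_fields` (data.frames) and a `log` of counts.
#' @export
filter_variants <- function(variants, config = variant_filter_config()) {
  has <- !is.na(variants$depth) & !is.na(variants$quality)
  missing <- variants[!has, , drop = FALSE]
  v <- variants[has, , drop = FALSE]
  bad_depth <- v$depth > config$max_depth
  bad_qual <- !bad_depth & v$quality < config$min_quality
  out <- list(retained = v[!bad_depth & !bad_qual, , drop = FALSE],
              removed_depth = v[bad_depth, , drop = FALSE],
              removed_quality = v[bad_qual, , drop = FALSE],
              missing_fields = missing)
  out$log <- c(input = nrow(variants), retained = nrow(out$retained),
               removed_depth = nrow(out$removed_depth),
               removed_quality = nrow(out$removed_quality),
               missing_fields = nrow(missing))
  out
}

#' Split variants into known and candidate-novel sets
#'
#' Known = present in the earlier catalogue (build 129). Candidate novel =
#' absent from both catalogues; sites only in the later build (132) are
#' dropped from the novel set (they are previously described, but were not
#' treated as "known" by the earlier annotation).
#'
#' @param variants Data.frame with an `id` column (and `chrom`/`pos` for
#'   positional matching).
#' @param ids129,ids132 Character vectors of catalogue identifiers, either
#'   variant IDs or `chrom:pos` keys.
#' @param by Match on `"id"` (default) or `"position"` (`chrom:pos`).
#' @return List: `known`, `novel`, `dropped_132`, and a `log` of counts.
#' @export
split_known_novel <- function(variants, ids129, ids132,
                              by = c("id", "position")) {
  by <- match.arg(by)
  key <- if (by == "id") variants$id else paste0(variants$chrom, ":", variants$pos)
  in129 <- !is.na(key) & key %in% ids129
  in132 <- !is.na(key) & key %in% ids132
  list(known = variants[in129, , drop = FALSE],
       novel = variants[!in129 & !in132, , drop = FALSE],
       dropped_132 = variants[!in129 & in132, , drop = FALSE],
       log = c(input = nrow(variants), known = sum(in129),
               novel = sum(!in129 & !in132),
               dropped_132 = sum(!in129 & in132)))
}

#' Restrict novel variants to well-covered peak regions
#'
#' Retains variants whose position falls inside a peak interval and whose
#' depth is at least `min_peak_reads`.
#'
#' @param variants Data.frame of candidate-novel variants.
#' @param peaks `GRanges` of peak regions (typically the differential
#'   regions; pass all peaks to widen the search).
#' @param config A [variant_filter_config()].
#' @return List: `retained`, `removed`, `log`.
#' @export
restrict_novel_to_peaks <- function(variants, peaks,
                                    config = variant_filter_config()) {
  if (nrow(variants) == 0) {
    return(list(retained = variants, removed = variants,
                log = c(input = 0L, retained = 0L, removed = 0L)))
  }
  pos <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, width = 1L))
  inside <- IRanges::overlapsAny(pos, peaks, ignore.strand = TRUE)
  keep <- inside & !is.na(variants$depth) &
    variants$depth >= config$min_peak_reads
  list(retained = variants[keep, , drop = FALSE],
       removed = variants[!keep, , drop = FALSE],
       log = c(input = nrow(variants), retained = sum(keep),
               removed = sum(!keep)))
}

#' Overlap variants with a GWAS catalogue, filtered by trait keywords
#'
#' A variant matches when it coincides with a catalogue SNP (same ID, or
#' same chrom/pos when IDs are absent) whose lowercase trait contains at
#' least one keyword as a substring.
#'
#' @param variants Data.frame with `id`, `chrom`, `pos`.
#' @param catalogue Data.frame with `snp_id`, `chrom`, `pos`, `trait`.
#' @param config A [variant_filter_config()].
#' @return `variants` with added `gwas_snp`, `gwas_trait`,
#'   `gwas_keyword` columns (`NA` when unmatched).
#' @export
gwas_overlap <- function(variants, catalogue,
                         config = variant_filter_config()) {
  trait_lc <- tolower(catalogue$trait)
  kw <- rep(NA_character_, nrow(catalogue))
  for (k in config$keywords) {
    hit <- is.na(kw) & grepl(k, trait_lc, fixed = TRUE)
    kw[hit] <- k
  }
  cat_ok <- catalogue[!is.na(kw), , drop = FALSE]
  kw_ok <- kw[!is.na(kw)]
  m_id <- match(variants$id, cat_ok$snp_id)
  m_pos <- match(paste0(variants$chrom, ":", variants$pos),
                 paste0(cat_ok$chrom, ":", cat_ok$pos))
  m <- ifelse(!is.na(m_id), m_id, m_pos)
  variants$gwas_snp <- cat_ok$snp_id[m]
  variants$gwas_trait <- cat_ok$trait[m]
  variants$gwas_keyword <- kw_ok[m]
  variants
}

#' Expand GWAS hits through linkage-disequilibrium proxies
#'
#' A sample variant is an LD proxy when the pairwise LD table links it to a
#' keyword-matching catalogue SNP with `r2 >= ld_r2_min` and
#' `|distance| <= ld_dist_max` (both bounds attained).
#'
#' @param variants Data.frame with `id` (plus GWAS columns from
#'   [gwas_overlap()] if already run).
#' @param ld Data.frame with `snp_a`, `snp_b`, `r2`, `distance`.
#' @param catalogue_ids IDs of the (keyword-matching) catalogue SNPs.
#' @param config A [variant_filter_config()].
#' @return `variants` with added `ld_proxy_of`, `ld_r2`, `ld_distance`
#'   columns (`NA` when not a proxy).
#' @export
ld_expand <- function(variants, ld, catalogue_ids,
                      config = variant_filter_config()) {
  ok <- ld$r2 >= config$ld_r2_min & abs(ld$distance) <= config$ld_dist_max
  edges <- rbind(
    data.frame(from = ld$snp_a[ok], to = ld$snp_b[ok],
               r2 = ld$r2[ok], distance = ld$distance[ok]),
    data.frame(from = ld$snp_b[ok], to = ld$snp_a[ok],
               r2 = ld$r2[ok], distance = ld$distance[ok]))
  edges <- edges[edges$to %in% catalogue_ids, , drop = FALSE]
  # keep the strongest partner per variant
  edges <- edges[order(edges$from, -edges$r2), , drop = FALSE]
  edges <- edges[!duplicated(edges$from), , drop = FALSE]
  m <- match(variants$id, edges$from)
  variants$ld_proxy_of <- edges$to[m]
  variants$ld_r2 <- edges$r2[m]
  variants$ld_distance <- edges$distance[m]
  variants
}

#' Categorize variants by histone-peak overlap in the two samples
#'
#' @param variants Data.frame with `chrom`, `pos`.
#' @param peaks_control,peaks_patient Pooled histone-mark peak `GRanges`
#'   per sample.
#' @return Character vector in `{both, control_only, patient_only, none}`.
#' @export
hm_overlap_category <- function(variants, peaks_control, peaks_patient) {
  if (nrow(variants) == 0) return(character(0))
  pos <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, width = 1L))
  in_c <- IRanges::overlapsAny(pos, peaks_control, ignore.strand = TRUE)
  in_p <- IRanges::overlapsAny(pos, peaks_patient, ignore.strand = TRUE)
  ifelse(in_c & in_p, "both",
         ifelse(in_c, "control_only",
                ifelse(in_p, "patient_only", "none")))
}

#' Run the full variant cascade
#'
#' Convenience wrapper chaining [filter_variants()], [split_known_novel()],
#' [restrict_novel_to_peaks()], [gwas_overlap()], [ld_expand()] and
#' [hm_overlap_category()], keeping each stage's count log.
#'
#' @param variants Data.frame from [read_variants()].
#' @param ids129,ids132 Catalogue ID vectors.
#' @param peaks `GRanges` used for the novel-in-peak restriction.
#' @param catalogue GWAS catalogue data.frame.
#' @param ld LD table data.frame.
#' @param peaks_control,peaks_patient Pooled per-sample peak `GRanges`.
#' @param config A [variant_filter_config()].
#' @param match_by Passed to [split_known_novel()].
#' @return List: `known` and `novel_in_peaks` annotated data.frames, plus
#'   `logs` (per-stage count vectors).
#' @export
annotate_variants <- function(variants, ids129, ids132, peaks, catalogue,
                              ld, peaks_control, peaks_patient,
                              config = variant_filter_config(),
                              match_by = "id") {
  flt <- filter_variants(variants, config)
  spl <- split_known_novel(flt$retained, ids129, ids132, by = match_by)
  res <- restrict_novel_to_peaks(spl$novel, peaks, config)
  kw_cat_ids <- {
    trait_lc <- tolower(catalogue$trait)
    hit <- Reduce(`|`, lapply(config$keywords, grepl, x = trait_lc,
                              fixed = TRUE), rep(FALSE, nrow(catalogue)))
    catalogue$snp_id[hit]
  }
  annotate <- function(v) {
    v <- gwas_overlap(v, catalogue, config)
    v <- ld_expand(v, ld, kw_cat_ids, config)
    v$hm_overlap <- hm_overlap_category(v, peaks_control, peaks_patient)
    v
  }
  list(known = annotate(spl$known),
       novel_in_peaks = annotate(res$retained),
       logs = list(filter = flt$log, split = spl$log, restrict = res$log))
}
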