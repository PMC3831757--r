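## Fragment-extension pileup peak caller.
##
## Single-end reads are deduplicated (one read per start position and
## strand), extended in silico to the mean fragment length (170 bp by
## default), and per-base overlap counts of the extended fragments are
## computed genome-wide. Maximal runs of pileup above a threshold become
## peaks; the summit is the leftmost position attaining the run maximum.

#' Peak-caller configuration
#'
#' @param fragment_length Mean sonication fragment length in bp; reads are
#'   extended to this length from their 5' end (default 170).
#' @param min_height Pileup threshold; with `inclusive = FALSE` (default) a
#'   position must exceed it strictly ("more than N overlapping fragments").
#'   The study values are 5 for the deeper-filtered disease sample and 10
#'   for the control.
#' @param inclusive Logical; if `TRUE` positions with pileup equal to
#'   `min_height` are also inside peaks.
#' @param input_ratio Maximum tolerated input-chromatin pileup at the summit
#'   as a fraction of the peak height (default 0.25); see
#'   [filter_by_input()].
#' @param motif_window Distance in bp from the summit searched for E-box
#'   matches (default 50).
#' @param motif_patterns Hexamer set scanned on the forward strand. The
#'   default (CACGTG, CACATG, CATGTG) is the E-box family CA\[C/T\]GTG
#'   together with its reverse complements, so a forward-strand scan is
#'   equivalent to scanning both strands.
#' @param strand_aware_dedup Logical; deduplicate on (chrom, start, strand)
#'   rather than (chrom, start).
#' @return A list of class `peakcall_config`.
#' @export
peakcall_config <- function(fragment_length = 170L, min_height = 10L,
                            inclusive = FALSE, input_ratio = 0.25,
                            motif_window = 50L,
                            motif_patterns = c("CACGTG", "CACATG", "CATGTG"),
                            strand_aware_dedup = TRUE) {
  stopifnot(fragment_length > 0, min_height >= 1,
            input_ratio >= 0, input_ratio < 1, motif_window >= 0)
  structure(list(fragment_length = as.integer(fragment_length),
                 min_height = as.integer(min_height),
                 inclusive = isTRUE(inclusive),
                 input_ratio = input_ratio,
                 motif_window = as.integer(motif_window),
                 motif_patterns = toupper(motif_patterns),
                 strand_aware_dedup = isTRUE(strand_aware_dedup)),
            class = "peakcall_config")
}

#' Retain one read per start position
#'
#' The 5'-most aligned coordinate as stored (BED start for both strands) is
#' the deduplication key; by default the strand is part of the key so that
#' bidirectional evidence at the same coordinate is preserved. Output is
#' sorted for determinism.
#'
#' @param reads Stranded `GRanges` of aligned reads.
#' @param strand_aware Include strand in the key (default `TRUE`).
#' @return Deduplicated, sorted `GRanges`.
#' @export
deduplicate_reads <- function(reads, strand_aware = TRUE) {
  if (length(reads) == 0) return(reads)
  key <- paste(as.character(GenomeInfoDb::seqnames(reads)),
               BiocGenerics::start(reads),
               if (strand_aware) as.character(BiocGenerics::strand(reads)) else "")
  out <- reads[!duplicated(key)]
  BiocGenerics::sort(out, ignore.strand = TRUE)
}

#' Extend reads to fragment length and compute genome-wide pileup
#'
#' A + read becomes the fragment `[start, start + L)`; a - read becomes
#' `[end - L, end)` (5'-anchored extension). Fragments running over a
#' chromosome edge are clipped, not discarded.
#'
#' @param reads Stranded `GRanges` (deduplicated).
#' @param config A [peakcall_config()].
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return An `RleList` of per-base fragment-overlap counts, one `Rle` per
#'   chromosome in `chrom_sizes`.
#' @export
extend_and_pileup <- function(reads, config = peakcall_config(), chrom_sizes) {
  stopifnot(!is.null(names(chrom_sizes)))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(GenomeInfoDb::seqnames(reads)),
                      levels = names(chrom_sizes)),
    ranges = IRanges::ranges(reads),
    strand = BiocGenerics::strand(reads))
  if (anyNA(as.integer(GenomeInfoDb::seqnames(gr))))
    stop("reads on chromosomes absent from chrom_sizes")
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  # fragments running over an edge are clipped, not discarded
  frag <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::resize(gr, config$fragment_length,
                                              fix = "start")))
  GenomicRanges::coverage(frag)
}

#' Call peaks from a pileup
#'
#' Peaks are maximal runs of positions whose pileup exceeds the threshold
#' (strictly, unless `config$inclusive`). Within each run the summit is the
#' leftmost position attaining the run maximum, and the height is that
#' maximum.
#'
#' @param cov `RleList` from [extend_and_pileup()].
#' @param config A [peakcall_config()].
#' @param total_mapped Total mapped reads in the library, used for
#'   `height_rpm = height * 1e6 / total_mapped`; `NA` heights-per-million
#'   when omitted.
#' @param sample_id,mark Labels stored on every peak.
#' @return `GRanges` with metadata columns `summit` (1-based), `height`,
#'   `height_rpm`, `sample_id`, `mark`, sorted by position.
#' @export
call_peaks <- function(cov, config = peakcall_config(), total_mapped = NA,
                       sample_id = NA_character_, mark = NA_character_) {
  lower <- config$min_height + if (config$inclusive) 0L else 1L
  out <- lapply(names(cov), function(chrom) {
    v <- IRanges::Views(cov[[chrom]],
                        IRanges::slice(cov[[chrom]], lower = lower,
                                       rangesOnly = TRUE))
    if (length(v) == 0) return(NULL)
    data.frame(chrom = chrom,
               start = BiocGenerics::start(v),
               end = BiocGenerics::end(v),
               summit = IRanges::viewWhichMaxs(v, na.rm = TRUE),
               height = IRanges::viewMaxs(v, na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(out$chrom,
                                 IRanges::IRanges(out$start, out$end))
    gr$summit <- as.integer(out$summit)
    gr$height <- as.integer(out$height)
  }
  gr$height_rpm <- if (length(gr)) gr$height * 1e6 / as.numeric(total_mapped)
                   else numeric(0)
  gr$sample_id <- if (length(gr)) sample_id else character(0)
  gr$mark <- if (length(gr)) mark else character(0)
  BiocGenerics::sort(gr)
}

#' Remove peaks enriched also in input chromatin
#'
#' A peak is discarded when the input-chromatin pileup at its summit reaches
#' `input_ratio` times the peak height (`input >= ratio * height`). The
#' number removed is reported via a message and an attribute.
#'
#' @param peaks `GRanges` from [call_peaks()].
#' @param input_cov Input-chromatin `RleList` built with the same fragment
#'   length.
#' @param config A [peakcall_config()].
#' @return Retained peaks, with `attr(, "n_removed")`.
#' @export
filter_by_input <- function(peaks, input_cov, config = peakcall_config()) {
  if (length(peaks) == 0) return(peaks)
  chroms <- as.character(GenomeInfoDb::seqnames(peaks))
  inp <- vapply(seq_along(peaks), function(i) {
    rl <- input_cov[[chroms[i]]]
    s <- peaks$summit[i]
    if (is.null(rl) || s > length(rl)) 0 else as.numeric(rl[s])
  }, numeric(1))
  drop <- inp >= config$input_ratio * peaks$height
  out <- peaks[!drop]
  attr(out, "n_removed") <- sum(drop)
  message(sum(drop), " peak(s) removed by input-chromatin filter")
  out
}

#' Cap peak lists at a common top-N
#'
#' N is the smallest per-sample peak count rounded down to a multiple of
#' `round_to`; each sample keeps its N best-ranked peaks. Ties are broken by
#' genomic order.
#'
#' @param peak_sets Named list of `GRanges`, one per sample, each carrying
#'   the ranking column.
#' @param round_to Rounding unit (default 1000).
#' @param score Metadata column to rank on (default `"height_rpm"`).
#' @param decreasing `TRUE` when larger scores rank higher (heights);
#'   use `FALSE` for p-values from an external caller.
#' @return Named list of truncated `GRanges` (each sorted by rank).
#' @export
select_top_peaks <- function(peak_sets, round_to = 1000L,
                             score = "height_rpm", decreasing = TRUE) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  counts <- vapply(peak_sets, length, integer(1))
  n <- (min(counts) %/% round_to) * round_to
  if (n == 0) {
    stop("smallest peak list has ", min(counts), " peaks, fewer than ",
         "round_to = ", round_to, "; use a smaller round_to")
  }
  lapply(peak_sets, function(gr) {
    s <- S4Vectors::mcols(gr)[[score]]
    if (is.null(s)) stop("ranking column '", score, "' missing")
    ord <- order(if (decreasing) -s else s,
                 as.character(GenomeInfoDb::seqnames(gr)),
                 BiocGenerics::start(gr))
    gr[ord[seq_len(n)]]
  })
}

#' Annotate peaks with E-box motif matches near the summit
#'
#' The window `[summit - w, summit + w + 5]` (so a hexamer starting up to
#' `w` bp from the summit is fully contained; 106 bp at the default
#' `w = 50`) is scanned on the forward strand for the pattern set, which is
#' closed under reverse complement.
#'
#' @param peaks `GRanges` with a `summit` column.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param config A [peakcall_config()].
#' @return `peaks` with an integer `motif_hit_count` column.
#' @seealso [ebox_summary()]
#' @export
scan_ebox <- function(peaks, genome, config = peakcall_config()) {
  if (length(peaks) == 0) {
    peaks$motif_hit_count <- integer(0)
    return(peaks)
  }
  w <- config$motif_window
  win <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(peaks),
    IRanges::IRanges(start = peaks$summit - w, end = peaks$summit + w + 5L))
  seqs <- Biostrings::DNAStringSet(fetch_sequence(genome, win))
  hits <- rep(0L, length(peaks))
  for (p in config$motif_patterns) {
    hits <- hits + Biostrings::vcountPattern(p, seqs)
  }
  peaks$motif_hit_count <- hits
  peaks
}

#' Summarize E-box annotation over a peak list
#'
#' @param peaks Output of [scan_ebox()].
#' @return List with `n_peaks`, `n_with_motif`, `fraction`.
#' @export
ebox_summary <- function(peaks) {
  n <- length(peaks)
  hit <- sum(peaks$motif_hit_count >= 1)
  list(n_peaks = n, n_with_motif = hit,
       fraction = if (n) hit / n else NA_real_)
}
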