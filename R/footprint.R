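## TSS footprint (metagene) profiles: aggregate read coverage around
## transcription start sites and the two-step joint normalization.

#' Construct a footprint profile object
#'
#' @param values Numeric vector of per-offset signal, offsets
#'   `-halfwidth .. +halfwidth`.
#' @param mark Track label.
#' @param n_genes Number of genes aggregated.
#' @param norm_state One of `"raw"`, `"sum_normalized"`, `"max_scaled"`.
#' @return Object of class `footprint_profile`.
#' @export
footprint_profile <- function(values, mark, n_genes,
                              norm_state = "raw") {
  stopifnot(length(values) %% 2 == 1, all(values >= 0) || norm_state != "raw")
  structure(list(mark = mark, values = as.numeric(values),
                 n_genes = as.integer(n_genes), norm_state = norm_state),
            class = "footprint_profile")
}

#' @export
print.footprint_profile <- function(x, ...) {
  cat("<footprint_profile>", x$mark, "-", length(x$values), "positions,",
      x$n_genes, "genes,", x$norm_state, "\n")
  invisible(x)
}

#' Average read coverage around TSSs
#'
#' For every gene passing the biotype filter, per-base read coverage is
#' extracted on `[tss - halfwidth, tss + halfwidth]`; windows of minus-strand
#' genes are reversed so that offsets run in the reading direction (disable
#' with `flip = FALSE`). The profile is the mean across genes; windows
#' running over a chromosome edge contribute zeros beyond it.
#'
#' @param reads Stranded `GRanges` of aligned reads (raw reads; extend them
#'   first with [extend_and_pileup()]-style resizing if fragment coverage is
#'   wanted).
#' @param genes Gene table from [read_gene_table()].
#' @param config A [differential_config()] (uses `footprint_halfwidth`).
#' @param biotype Biotype filter, default `"protein_coding"`; `NULL` keeps
#'   all genes.
#' @param flip Orient windows by gene strand (default `TRUE`).
#' @param mark Label stored on the profile.
#' @return A [footprint_profile()] of length `2 * halfwidth + 1`.
#' @export
tss_footprint <- function(reads, genes, config = differential_config(),
                          biotype = "protein_coding", flip = TRUE,
                          mark = NA_character_) {
  if (!is.null(biotype)) genes <- genes[genes$biotype %in% biotype, ]
  if (nrow(genes) == 0) stop("no genes pass the biotype filter")
  hw <- config$footprint_halfwidth
  len <- 2L * hw + 1L
  cov <- GenomicRanges::coverage(GenomicRanges::granges(reads))
  acc <- numeric(len)
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    rl <- if (ch %in% names(cov)) cov[[ch]] else S4Vectors::Rle(0L, 0)
    s <- genes$tss[i] - hw
    e <- genes$tss[i] + hw
    v <- numeric(len)
    cs <- max(1L, s)
    ce <- min(length(rl), e)
    if (cs <= ce) {
      v[(cs - s + 1L):(ce - s + 1L)] <- as.numeric(rl[cs:ce])
    }
    if (flip && genes$strand[i] == "-") v <- rev(v)
    acc <- acc + v
  }
  footprint_profile(acc / nrow(genes), mark = mark, n_genes = nrow(genes))
}

#' Jointly normalize footprint profiles
#'
#' Step 1 rescales every profile to a common total sum over its positions
#' (the number of positions, so a flat profile sits at 1). Step 2 divides
#' all profiles by the single global maximum across profiles, so the
#' maximal observed enrichment over all tracks equals 1. Applying the
#' function to its own output changes nothing.
#'
#' @param profiles List of [footprint_profile()] objects of equal length.
#' @param target_sum Common sum after step 1; defaults to the profile
#'   length (2001 at the default half-width).
#' @return List of normalized profiles (`norm_state = "max_scaled"`).
#' @export
normalize_footprints <- function(profiles, target_sum = NULL) {
  stopifnot(length(profiles) >= 1)
  lens <- vapply(profiles, function(p) length(p$values), integer(1))
  stopifnot(length(unique(lens)) == 1)
  if (is.null(target_sum)) target_sum <- lens[1]
  sums <- vapply(profiles, function(p) sum(p$values), numeric(1))
  if (any(sums <= 0)) {
    stop("all-zero profile (", paste(vapply(profiles[sums <= 0],
         function(p) p$mark, character(1)), collapse = ", "),
         "): cannot sum-normalize")
  }
  step1 <- lapply(profiles, function(p) {
    p$values <- p$values * target_sum / sum(p$values)
    p$norm_state <- "sum_normalized"
    p
  })
  gmax <- max(vapply(step1, function(p) max(p$values), numeric(1)))
  lapply(step1, function(p) {
    p$values <- p$values / gmax
    p$norm_state <- "max_scaled"
    p
  })
}

#' Footprint profiles as a long data.frame
#'
#' @param profiles List of [footprint_profile()] objects.
#' @return Data.frame with `mark`, `offset`, `value`.
#' @export
footprint_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    hw <- (length(p$values) - 1L) %/% 2L
    data.frame(mark = p$mark, offset = seq(-hw, hw), value = p$values,
               stringsAsFactors = FALSE)
  }))
}
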