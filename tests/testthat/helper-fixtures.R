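# Shared fixtures. The default-scale study simulation is expensive enough
# to build once and reuse across test files.

make_reads <- function(chrom, start, width = 50L, strand = "+") {
  gr <- GenomicRanges::GRanges(rep(chrom, length.out = length(start)),
                               IRanges::IRanges(start, width = width),
                               strand = rep(strand, length.out = length(start)))
  S4Vectors::metadata(gr)$total_mapped <- length(gr)
  gr
}

make_regions <- function(chrom, start, end, ...) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

# small study: fast enough for unit tests of the generator itself
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 1L, chrom_length = 150000L,
         n_genes = 12L, n_repeats = 8L, n_peaks_hm = 8L,
         n_peaks_tf = 10L, n_variants = 60L, n_input_artifacts = 1L),
    list(...))
  do.call(sim_config, args)
}

.cache <- new.env(parent = emptyenv())

# the study at its default (documented) conditions, seed 0
default_sim <- function() {
  if (is.null(.cache$sim)) .cache$sim <- simulate_study(sim_config(seed = 0))
  .cache$sim
}

default_run <- function() {
  if (is.null(.cache$run)) .cache$run <- run_pipeline(sim = default_sim())
  .cache$run
}

mkvar <- function(n = 0, ...) {
  base <- data.frame(
    sample_id = "patient", chrom = "chr1",
    pos = seq_len(max(n, 1)) * 100L,
    id = sprintf("v%03d", seq_len(max(n, 1))),
    ref = "A", alt = "G", quality = 100, depth = 50,
    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

test_genes <- function() {
  data.frame(
    gene_id = c("G1", "G2", "G3"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(1000L, 5000L, 2000L),
    end = c(3000L, 8000L, 4000L),
    biotype = c("protein_coding", "protein_coding", "lincRNA"),
    tss = c(1000L, 8000L, 2000L),
    tes = c(3000L, 5000L, 4000L),
    stringsAsFactors = FALSE)
}
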