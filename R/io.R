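## Readers/writers for the standard formats the pipeline touches.
##
## Internal convention: every interval lives in a GRanges (1-based, closed).
## BED-family files (0-based half-open) are converted by rtracklayer on
## import/export; VCF positions stay 1-based and are used directly.

.NARROWPEAK_COLS <- c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer")

#' Read genomic intervals from BED or narrowPeak
#'
#' @param path Path to a tab-separated BED3+/BED6 or ENCODE narrowPeak file.
#' @param dialect `"bed"` or `"narrowPeak"`. For narrowPeak the summit offset
#'   (column 10) is preserved: a `summit` metadata column holds the absolute
#'   1-based summit position (`NA` when the offset is -1).
#' @return A `GRanges`. narrowPeak input additionally carries
#'   `signalValue`, `pValue`, `qValue` and `summit` metadata columns.
#' @export
read_intervals <- function(path, dialect = c("bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  nf <- count.fields(path, sep = "\t", comment.char = "#", quote = "")
  if (length(nf) == 0) return(GenomicRanges::GRanges())
  bad <- which(nf < 3)
  if (length(bad)) {
    stop("malformed interval file '", path, "': line ", bad[1],
         " has ", nf[bad[1]], " column(s), need >= 3")
  }
  extra <- if (dialect == "narrowPeak") .NARROWPEAK_COLS else NULL
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED", extraCols = extra),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (any(BiocGenerics::width(gr) < 1)) {
    stop("interval with start >= end in '", path, "'")
  }
  if (dialect == "narrowPeak") {
    off <- gr$peak
    gr$summit <- ifelse(is.na(off) | off < 0, NA_integer_,
                        BiocGenerics::start(gr) + off)
    gr$peak <- NULL
  }
  gr
}

#' Write genomic intervals to BED or narrowPeak
#'
#' narrowPeak output takes the signal column from `height_rpm` (falling back
#' to `signalValue`, then to the BED score) and the summit offset from a
#' `summit` metadata column (`-1` when absent).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param dialect `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path, dialect = c("bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    rtracklayer::export(gr, path, format = "BED")
    return(invisible(path))
  }
  n <- length(gr)
  nm <- if (!is.null(gr$name)) gr$name else paste0("peak_", seq_len(n))
  sig <- if (!is.null(gr$height_rpm)) gr$height_rpm
         else if (!is.null(gr$signalValue)) gr$signalValue
         else rep(0, n)
  pv <- if (!is.null(gr$pValue)) gr$pValue else rep(-1, n)
  qv <- if (!is.null(gr$qValue)) gr$qValue else rep(-1, n)
  off <- if (!is.null(gr$summit)) {
    ifelse(is.na(gr$summit), -1L, gr$summit - BiocGenerics::start(gr))
  } else rep(-1L, n)
  score <- if (!is.null(gr$height)) pmin(1000L, as.integer(gr$height)) else rep(0L, n)
  strnd <- as.character(BiocGenerics::strand(gr))
  strnd[strnd == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = nm, score = score, strand = strnd,
    signalValue = sig, pValue = pv, qValue = qv, peak = off,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned single-end reads
#'
#' Each read becomes one range with strand. The total number of mapped
#' records is attached as `metadata(gr)$total_mapped` for RPM normalization;
#' for BAM input, unmapped records are skipped and do not count.
#'
#' @param path BED6 or BAM file of single-end alignments.
#' @param fmt `"bed"` or `"bam"`.
#' @return A stranded `GRanges` with `metadata()$total_mapped`.
#' @export
read_reads <- function(path, fmt = c("bed", "bam")) {
  fmt <- match.arg(fmt)
  if (fmt == "bed") {
    gr <- read_intervals(path, "bed")
  } else {
    p <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "qwidth"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    res <- Rsamtools::scanBam(path, param = p)[[1]]
    keep <- !is.na(res$pos)
    gr <- GenomicRanges::GRanges(
      seqnames = res$rname[keep],
      ranges = IRanges::IRanges(start = res$pos[keep],
                                width = res$qwidth[keep]),
      strand = res$strand[keep])
  }
  S4Vectors::metadata(gr)$total_mapped <- length(gr)
  gr
}

#' Fetch an uppercase sequence for an interval
#'
#' Intervals extending beyond the chromosome are clipped, so the returned
#' string may be shorter than the request.
#'
#' @param genome A named `DNAStringSet` (or path to a FASTA file).
#' @param gr A `GRanges` (one or more intervals).
#' @return Character vector of uppercase sequences, one per interval.
#' @export
fetch_sequence <- function(genome, gr) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(genome))
  if (length(unknown)) stop("chromosome(s) not in genome: ",
                            paste(unknown, collapse = ", "))
  lens <- Biostrings::width(genome)[match(chroms, names(genome))]
  s <- pmax(1L, BiocGenerics::start(gr))
  e <- pmin(lens, BiocGenerics::end(gr))
  out <- character(length(gr))
  ok <- s <= e
  out[ok] <- toupper(as.character(Biostrings::subseq(
    genome[chroms[ok]], start = s[ok], end = e[ok])))
  out
}

#' Read variant sites from a VCF file
#'
#' Depth is taken from INFO/DP when present, otherwise as the sum of the
#' per-sample FORMAT/DP values. A record missing QUAL or DP is kept and
#' flagged via `missing_fields` rather than dropped.
#'
#' @param path VCF 4.x file (plain text).
#' @param sample_id Label stored in the `sample_id` column; defaults to the
#'   first sample name in the VCF header, or the file name.
#' @return A data.frame with columns `sample_id`, `chrom`, `pos` (1-based),
#'   `id`, `ref`, `alt`, `quality`, `depth`, `missing_fields`.
#' @export
read_variants <- function(path, sample_id = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  hdr <- VariantAnnotation::header(vcf)
  has_info_dp <- "DP" %in% rownames(VariantAnnotation::info(hdr))
  has_geno_dp <- "DP" %in% rownames(VariantAnnotation::geno(hdr))
  if (!has_info_dp && !has_geno_dp) {
    stop("VCF '", path, "' defines no DP field in INFO or FORMAT; ",
         "re-call variants with depth annotation (e.g. bcftools with DP)")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0) {
    if (is.null(sample_id)) sample_id <- character(0)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), id = character(0),
                      ref = character(0), alt = character(0),
                      quality = numeric(0), depth = numeric(0),
                      missing_fields = logical(0)))
  }
  fx <- VariantAnnotation::fixed(vcf)
  alt <- VariantAnnotation::alt(vcf)
  alt1 <- vapply(as(alt, "CharacterList"), function(a)
    if (length(a)) a[[1]] else NA_character_, character(1))
  dp <- rep(NA_real_, n)
  if (has_info_dp) {
    idp <- VariantAnnotation::info(vcf)$DP
    if (!is.null(idp)) dp <- as.numeric(idp)
  }
  if (has_geno_dp && anyNA(dp)) {
    gdp <- VariantAnnotation::geno(vcf)$DP
    if (!is.null(gdp)) {
      gsum <- rowSums(matrix(as.numeric(gdp), nrow = n), na.rm = TRUE)
      gsum[apply(matrix(is.na(gdp), nrow = n), 1, all)] <- NA_real_
      dp[is.na(dp)] <- gsum[is.na(dp)]
    }
  }
  if (is.null(sample_id)) {
    smp <- colnames(vcf)
    sample_id <- if (length(smp)) smp[1] else basename(path)
  }
  qual <- as.numeric(fx$QUAL)
  ids <- names(rr)
  # readVcf keys unnamed records as chrom:pos_ref/alt; treat those as missing
  auto <- paste0(as.character(GenomeInfoDb::seqnames(rr)), ":",
                 BiocGenerics::start(rr), "_", as.character(fx$REF), "/", alt1)
  ids[!is.na(ids) & ids == auto] <- NA_character_
  data.frame(
    sample_id = sample_id,
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    id = ids,
    ref = as.character(fx$REF),
    alt = alt1,
    quality = qual,
    depth = dp,
    missing_fields = is.na(qual) | is.na(dp),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a variant table as a minimal VCF 4.2 file
#'
#' Counterpart of [read_variants()]; writes DP into INFO.
#'
#' @param variants Data.frame with `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `quality`, `depth` columns.
#' @param path Output path.
#' @param sample_id Sample name placed in the header line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_id = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")), con)
  if (nrow(variants)) {
    ids <- variants$id
    ids[is.na(ids) | ids == ""] <- "."
    lines <- paste(variants$chrom, variants$pos, ids, variants$ref,
                   variants$alt,
                   format(variants$quality, trim = TRUE, scientific = FALSE),
                   "PASS", paste0("DP=", as.integer(variants$depth)),
                   "GT", "0/1", sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a header line and six columns: `gene_id`, `chrom`, `strand`,
#' `start`, `end`, `biotype` (1-based closed gene body). TSS and 3' end
#' (`tss`, `tes`) are derived from strand.
#'
#' @param path TSV file.
#' @return Data.frame with derived `tss` and `tes` columns.
#' @export
read_gene_table <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "start", "end", "biotype")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("gene table '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id in '", path, "'")
  if (!all(g$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tes <- ifelse(g$strand == "+", g$end, g$start)
  g
}

#' Read a generic headered TSV (GWAS catalogue, LD table, qPCR table)
#'
#' @param path TSV file with a header line.
#' @param required Character vector of column names that must be present.
#' @return Data.frame.
#' @export
read_tsv_table <- function(path, required = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) stop("table '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Read a variant ID list (one ID per line, or a TSV with an `id` column)
#'
#' @param path File emulating a dbSNP build export.
#' @return Character vector of IDs.
#' @export
read_id_list <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) return(character(0))
  if (grepl("\t", first) || identical(first, "id")) {
    read.delim(path, stringsAsFactors = FALSE)$id
  } else {
    readLines(path)
  }
}

## internal: write a data.frame as headered TSV
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
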