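# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no IRanges coverage/slice/overlap machinery): per-base
# vectors, nested loops and regexes only.

# per-base fragment pileup on one chromosome, by interval stabbing
oracle_pileup <- function(starts, ends, strands, frag_len, chrom_len) {
  cov <- integer(chrom_len)
  for (i in seq_along(starts)) {
    fs <- if (strands[i] == "+") starts[i] else ends[i] - frag_len + 1L
    fe <- fs + frag_len - 1L
    fs <- max(1L, fs); fe <- min(chrom_len, fe)
    if (fs <= fe) cov[fs:fe] <- cov[fs:fe] + 1L
  }
  cov
}

# maximal runs of cov > threshold (or >= when inclusive), leftmost-max summit
oracle_runs <- function(cov, threshold, inclusive = FALSE) {
  above <- if (inclusive) cov >= threshold else cov > threshold
  out <- NULL
  i <- 1L
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      seg <- cov[i:j]
      out <- rbind(out, data.frame(start = i, end = j,
                                   summit = i + which.max(seg) - 1L,
                                   height = max(seg)))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# E-box oracle: scans CA[CT]GTG on both strands with regexes.
# hit: TRUE when either strand carries a match.
# count: forward-strand occurrences of the strand-closed pattern family
# (a palindromic CACGTG site is one site, not two).
oracle_ebox <- function(seq) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  hit <- grepl("CA[CT]GTG", seq) || grepl("CA[CT]GTG", rc)
  m <- gregexpr("(?=(CACGTG|CACATG|CATGTG))", seq, perl = TRUE)[[1]]
  count <- if (m[1] == -1) 0L else length(m)
  list(hit = hit, count = count)
}

# exhaustive nearest-TSS search with smallest-gene_id tie-break
oracle_nearest <- function(anchor_chrom, anchor_pos, genes) {
  g <- genes[order(genes$gene_id), ]
  same <- g[g$chrom == anchor_chrom, ]
  if (nrow(same) == 0) same <- g
  d <- abs(same$tss - anchor_pos)
  same$gene_id[which.min(d)]
}

# fraction of a region covered by the union of repeat intervals
oracle_repeat_frac <- function(r_start, r_end, rep_starts, rep_ends) {
  covered <- logical(r_end - r_start + 1L)
  for (i in seq_along(rep_starts)) {
    a <- max(r_start, rep_starts[i]); b <- min(r_end, rep_ends[i])
    if (a <= b) covered[(a - r_start + 1L):(b - r_start + 1L)] <- TRUE
  }
  mean(covered)
}

# per-base union of two interval sets
oracle_union <- function(starts, ends, chrom_len) {
  inset <- logical(chrom_len)
  for (i in seq_along(starts)) inset[starts[i]:ends[i]] <- TRUE
  r <- rle(inset)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  data.frame(start = s[r$values], end = e[r$values])
}
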