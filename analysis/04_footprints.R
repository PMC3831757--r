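#!/usr/bin/env Rscript
# Stage 4: TSS footprints.
#
# For every protein-coding gene, per-base read coverage is averaged over
# +/- 1000 bp around the TSS (2001 positions, minus-strand genes flipped
# into reading direction). Profiles are normalized to a common sum and
# then jointly scaled so the maximal enrichment across marks equals 1.

suppressMessages(library(chromdiff))

sim <- simulate_study(sim_config(seed = 0))
dir.create("results", showWarnings = FALSE)

profiles <- lapply(sim$config$marks, function(mk)
  tss_footprint(sim$reads$patient[[mk]], sim$genes,
                differential_config(), mark = mk))
profiles <- normalize_footprints(profiles)
tab <- footprint_table(profiles)
write.table(tab, "results/footprints.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Normalized TSS footprints over",
    sum(sim$genes$biotype == "protein_coding"), "protein-coding genes:\n")
for (p in profiles) {
  cat(sprintf("  %-8s sum %.3f  max %.3f  at offset %+d\n", p$mark,
              sum(p$values), max(p$values),
              which.max(p$values) - 1001L))
}
cat("The promoter marks (H3K4me3, H3K27ac) peak at the TSS and dominate",
    "\nH3K4me1, whose planted sites are mostly distal.\n")
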