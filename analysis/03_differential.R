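#!/usr/bin/env Rscript
# Stage 3: differential histone-modification regions.
#
# Per mark: peaks are called in both samples, capped at a common top-N,
# union-merged into candidate regions, cleared of repeat-dominated regions
# (> 80% simpleRepeat coverage), RPM-counted in both libraries, and ranked
# by the RPM difference in both directions. Each selected region is
# assigned the gene with the closest TSS, and regions are classified into
# the six genomic-distribution categories (3 marks x 2 directions,
# TSS-proximal vs not).

suppressMessages(library(chromdiff))

sim <- simulate_study(sim_config(seed = 0))
run <- run_pipeline(sim = sim)
dir.create("results", showWarnings = FALSE)

for (mk in sim$config$marks) {
  for (dir in names(run$differential[[mk]])) {
    gr <- run$differential[[mk]][[dir]]
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr),
                     end = BiocGenerics::end(gr),
                     as.data.frame(S4Vectors::mcols(gr)))
    write.table(df, sprintf("results/differential_%s_%s.tsv", mk, dir),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
write.table(run$genomic_distribution, "results/genomic_distribution.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
pres <- do.call(rbind, lapply(names(run$presence), function(mk)
  data.frame(mark = mk, run$presence[[mk]])))
write.table(pres, "results/gene_peak_presence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Genomic distribution of differential regions:\n")
print(run$genomic_distribution, row.names = FALSE)
cat("\nGenes with peaks by sample (both / control-only / patient-only):\n")
print(pres, row.names = FALSE)
cat("\nH3K4me3 regions concentrate at TSSs; H3K4me1 regions are mostly",
    "distal,\nreflecting the planted promoter/enhancer site fractions.\n")
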