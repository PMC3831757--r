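---
title: "Methods: differential chromatin analysis of tissue ChIP-seq"
author: "chromdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential chromatin analysis of tissue ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

chromdiff reimplements, as a tested pipeline over synthetic data with
recorded truth, the computational core of a two-sample tissue ChIP-seq
comparison: a diseased liver (alcoholic steatohepatitis) versus a normal
liver, assayed for three activating histone marks (H3K4me1 at enhancers,
H3K4me3 at promoters, H3K27ac at both) and the E-box binding transcription
factor USF1. The pipeline covers TF peak calling, differential
histone-modification ranking with gene assignment, TSS footprint profiles,
genomic-distribution classification, a regulatory SNP filtering/annotation
cascade, and the qPCR enrichment call. Read alignment, external peak
callers, de novo motif discovery, genotype-likelihood models, consequence
prediction and GO enrichment are out of scope; their outputs (aligned
reads, peak lists, VCFs) are inputs here.

# The peak caller

Single-end reads (50 bp in the emulated design) are reduced to one read
per start position and strand — the deduplication key includes strand so
that bidirectional evidence at one coordinate survives; a strand-blind
mode is available (`strand_aware_dedup = FALSE`). Each read is then
extended in silico to the mean sonication fragment length, 170 bp, from
its 5' end, and the per-base overlap count of extended fragments is
computed genome-wide (`extend_and_pileup()`; fragments running over a
chromosome edge are clipped, not discarded). Peaks are maximal runs of
positions whose pileup strictly exceeds a threshold: 10 for the control
TF library and 5 for the patient TF library, compensating for the ~3x
depth difference between the two. "More than N reads" is read as a strict
inequality; `inclusive = TRUE` switches to `>=`. The summit is the
leftmost position attaining the run maximum — leftmost purely for
determinism. Note that a stricter threshold can *split* a peak whose
plateau dips, so peak counts are not monotone in the threshold; covered
bases are, and every stricter-threshold peak is contained in a
looser-threshold one.

Two derived annotations follow:

* **Input filtering.** The source material says only that peaks "enriched
  also in input chromatin" were removed, without a criterion. Our
  operationalization: a peak is dropped when the input pileup at its
  summit reaches `input_ratio` (default 0.25) times the peak height. The
  ratio is a config knob, and the removal count is always reported.
* **E-box scan.** The window `[summit - 50, summit + 55]` (106 bp, so a
  hexamer *starting* up to 50 bp from the summit is fully contained) is
  scanned on the forward strand for CACGTG, CACATG and CATGTG. This set
  is closed under reverse complement, so the forward scan is equivalent
  to scanning CA[C/T]GTG on both strands; a palindromic CACGTG site
  counts once.

Peak heights are reported both raw and in reads per million mapped
(RPM). When peak lists from an external caller are supplied (narrowPeak),
their p-value column can rank them in `select_top_peaks()` instead.

# Differential regions

Because peak counts scale with library depth, per-sample peak lists are
first capped at a common N: the smallest list size rounded down to a
multiple of `round_to`, every sample keeping its N best-ranked peaks
(ties broken by genomic order). At study scale the rounding unit is 1000;
at the synthetic scale used throughout this package it is 10.

Capped lists from the two samples are union-merged (`merge_peak_regions()`)
so that a region identified in either sample is counted exactly once.
Regions more than 80% covered (strictly) by the simpleRepeat track are
removed. Reads overlapping each region by at least one base are counted in
both libraries and normalized to RPM — the delta is computed on RPM, not
raw counts, because the libraries differ 2-3x in depth. Each direction's
top `n_top` regions by delta become the differentially enriched sets; no
distributional model or skew correction is applied, matching the source
design's deliberately assumption-free top-N choice.

Each selected region is assigned the gene with the closest TSS. The
distance anchor is the summit when the region carries one, otherwise the
midpoint (symmetric; the source is silent on the anchor). Distances are
signed in the gene's reading direction and ties go to the
lexicographically smaller gene ID. Genomic-distribution classification
uses all annotated genes regardless of biotype: a region is TSS-proximal
when it overlaps any TSS +/- 2 kb window and intragenic when it overlaps
any gene body, yielding the six-category tally (3 marks x 2 directions,
TSS vs non-TSS).

# TSS footprints

For every protein-coding gene, per-base read coverage is extracted on
+/- 1000 bp around the TSS (2001 positions). Windows of minus-strand genes
are reversed so offsets run in reading direction (`flip = FALSE`
reproduces unoriented aggregation); the profile is the mean across genes.
Raw reads are counted rather than extended fragments — the source
describes counting "reads" — and fragment extension can be applied
upstream if desired.

Normalization is two-step: (1) every mark's profile is rescaled to a
common total over the 2001 positions — the constant is 2001, so a flat
profile sits at 1; any constant gives identical final output, this one is
interpretable; (2) all profiles are divided by the single global maximum
across marks, so the maximal observed enrichment equals 1 exactly. The
scaling is global rather than per-mark deliberately: it preserves the
biological observation that the promoter marks H3K4me3/H3K27ac dominate
H3K4me1 at the TSS. The composition is idempotent, and step 1's equal-sum
identity survives step 2.

# The variant cascade

One VCF per individual is consumed (upstream calling on merged
histone-mark alignments is out of scope). Stages, in order, with every
count logged so input = retained + removed at each stage:

1. **Depth/quality filter**: sites with depth > 100 are removed as likely
   repetitive, sites with quality < 50 are removed; both boundaries
   retain (depth 100, quality 50 pass). Depth is the site DP (INFO DP,
   else summed FORMAT DP); records missing either field go to a separate
   bucket, never silently kept.
2. **Known/novel split** against two versioned catalogue ID lists
   (emulating dbSNP builds 129 and 132): known = present in the older
   build; candidate novel = absent from both; sites only in the newer
   build are dropped from the novel set. Matching is by ID, with a
   positional (`chrom:pos`) mode for allele-less lists.
3. **Novel-in-peak restriction**: novel sites are kept when they fall
   inside a peak region with depth >= 10. The default peak set is the
   differential regions (the ambiguous reading "peak regions" could also
   mean all peaks; pass any `GRanges` to widen it).
4. **GWAS keyword overlap**: a variant matches when it coincides with a
   catalogue SNP (ID, else position) whose lowercase trait contains one
   of ten liver/lipid/glucose keywords as a substring — case-insensitive,
   no stemming, for transparency and reproducibility.
5. **LD proxy expansion**: a variant linked in the pairwise LD table to a
   keyword-matching catalogue SNP with r2 >= 0.8 and distance <= 500 kb
   (both bounds attained — "threshold" and "limit" read as inclusive) is
   annotated as a proxy, keeping its strongest partner.
6. **Histone-peak overlap category**: each variant is labelled
   both / control_only / patient_only / none by point membership in the
   pooled per-sample histone peaks; the labels partition the set.

# The qPCR statistic

The background level is mean + 2 SD of the negative-control regions; the
sample (n-1) SD is used — the source does not state the divisor, and the
sample SD is the conservative choice (`population = TRUE` switches). A
region is called positive when its enrichment strictly exceeds two-fold
background. ChIP-seq/qPCR agreement is the squared Pearson correlation of
paired heights and enrichment values, undefined (reported `NA`) below 3
pairs or under zero variance.

# The synthetic study and what it does (not) show

`simulate_study()` generates the complete study under one seed,
byte-reproducibly: a uniform-random genome (2 chromosomes x 400 kb), 80
non-overlapping genes (54% protein-coding, matching the roughly half
protein-coding share of an annotated genome), simple repeats, planted
peak sites, reads, and variant/GWAS/LD/qPCR tables, with every planted
object recorded in truth tables.

Design choices the scale of which a user may want to know:

* **Sites.** 50 sites per histone mark, 60 for the TF, mean width 300 bp.
  Promoter-associated marks are planted mostly at TSSs (fractions 0.7 for
  H3K4me3, 0.45 for H3K27ac, 0.15 for H3K4me1; 0.5 for the TF), which is
  what makes the footprint and genomic-distribution outputs structured.
  70% of histone sites (80% of TF sites) are present in both samples; the
  rest split evenly into sample-only sites. 40% of shared histone sites
  carry a differential effect: the favored sample's rate is exactly
  `differential_fold` (default 3) times the shared site height. Shared
  site heights are log-normal around multiplier 20 (SD 0.3 in log space)
  with mild per-sample noise (SD 0.2) at non-differential sites only —
  noise on top of the fold would silently shrink planted effects.
* **Reads.** Background read starts are Poisson at 0.01/bp; a planted
  site of multiplier m adds Poisson((m - 1) x rate x width) reads whose
  170 bp fragments each contain the planted summit, as ChIP fragments
  contain the bound site. (A uniform-start model inside the site would
  place the expected pileup maximum off the site center, because 50 bp
  reads extend asymmetrically.) The patient histone libraries are 1.7x
  deeper, the patient TF library 0.35x as deep — the depth imbalances the
  per-sample thresholds exist to compensate for. `peak_base_rate`
  decouples the in-peak rate from the background rate so a zero-background
  genome can still carry peaks.
* **Input.** The input-chromatin track is background plus two planted
  artifact regions also spiked into both TF ChIPs; the input filter is
  expected to remove them.
* **Variants.** 400 sites: 60% inside histone peaks; depth mixture (10%
  above 100, 15% below 10); 15% low quality; 50% known in the older
  catalogue build, 15% more only in the newer; 15% with GWAS catalogue
  entries (60% keyword-matching traits); LD edges with r2 in [0.4, 1]
  and distances up to 800 kb so both bounds are exercised. Repeats are
  placed clear of planted sites so the repeat filter cannot erase
  recoverable truth.
* **qPCR.** 13 positive regions at shared TF sites and 4 negatives, the
  validation design of the emulated study.

What passing tests on this generator show: the implementation of every
operation is correct against independent brute-force oracles, planted
truth is recovered under realistic depth, and the whole pipeline is a
deterministic function of its seed. What they do not show: behavior under
real-genome mappability, GC bias, duplicated and repetitive sequence,
chromatin-state-dependent fragment size, or sequencing error — none of
which the generator models. Peak/motif counts from the real tissue data
therefore cannot be reproduced here; at desk scale the pipeline's claims
are correctness and truth-recovery claims, not biological ones.

# Numerical conventions

All intervals are GRanges (1-based, closed) internally; BED-family files
are converted at the I/O boundary and VCF positions stay 1-based. Problem
sizes throughout (800 kb genome, ~10-20k reads per track, 400 variants)
were chosen so the full suite and a complete pipeline run finish in
seconds while every planted effect is still recoverable with wide
margins. Ties are always broken deterministically (leftmost summit,
genomic order, smaller gene ID). Degenerate inputs fail loudly: empty
annotation, all-zero footprints, zero mapped reads, backgrounds <= 0 and
sub-2 negative-control sets are errors, not silent results.
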