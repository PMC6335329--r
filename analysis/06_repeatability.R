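#!/usr/bin/env Rscript
# Stage 6: subsampling repeatability. For disjoint gene groups and a grid of
# sample sizes n, two disjoint n-sample replicates are drawn from disease
# A's cases, all pair correlations recomputed in each, and the agreement
# (the correlation between the two pair-correlation vectors) recorded.
# Agreement approaching 1 means the co-methylation estimates are repeatable
# at that sample size.

library(comethdiff)

genes <- read_beta_matrix("results/data/diseaseA_genes.tsv")
phen <- read_phenotypes("results/data/diseaseA_phenotypes.tsv")

cfg <- repeatability_config(
  n_groups = 5L, group_size = 20L,
  sample_sizes = c(2L, 5L, 10L, 25L, 50L, 75L, 100L, 125L, 150L),
  seed = 20260106L)
curve <- run_repeatability(genes, phen, group = "case", cfg = cfg)
write.table(curve, "results/repeatability_curve.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

med <- aggregate(agreement ~ n, curve, median)
cat("Median replicate agreement across the 5 gene groups:\n")
print(med, row.names = FALSE)
small <- med$agreement[med$n == 5]
big <- med$agreement[med$n == 150]
cat(sprintf("\nAgreement rises from %.3f at n = 5 to %.3f at n = 150:\n", small, big))
cat("replicate pair-correlation vectors are dominated by sampling noise at\n")
cat("small n and converge on the underlying co-methylation structure as n\n")
cat("grows; the ceiling reflects how much true correlation spread the\n")
cat("simulated data carries relative to the residual noise at n = 150.\n")
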