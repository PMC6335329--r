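#!/usr/bin/env Rscript
# Stage 5: intersect the two diseases' large-change pair sets, apply the
# strict |delta| > 0.8 filter, export the unique-gene list, and compare what
# was recovered against the simulated ground truth.

library(comethdiff)

out <- "results"
large_a <- read_pair_table(file.path(out, "diseaseA_large_change.tsv"))
large_b <- read_pair_table(file.path(out, "diseaseB_large_change.tsv"))
shared <- intersect_pairs(large_a, large_b)
write.table(shared, file.path(out, "shared_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

delta_a <- filter_by_delta(large_a, 0.8)
delta_b <- filter_by_delta(large_b, 0.8)
shared_delta <- intersect_pairs(delta_a, delta_b)
write.table(shared_delta, file.path(out, "shared_pairs_delta0.8.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
genes <- unique_genes(shared)
write_gene_list(genes, file.path(out, "shared_unique_genes.txt"))

cat(sprintf("Large-change pairs: disease A %d, disease B %d, shared %d\n",
            nrow(large_a), nrow(large_b), nrow(shared)))
cat(sprintf("|delta| > 0.8: A %d, B %d, shared %d\n",
            nrow(delta_a), nrow(delta_b), nrow(shared_delta)))
cat("Shared pairs and their per-disease correlations:\n")
print(shared)
cat(sprintf("%d unique genes exported for enrichment tools\n", length(genes)))

truth_a <- read.delim("results/data/diseaseA_truth_pairs.tsv")
truth_b <- read.delim("results/data/diseaseB_truth_pairs.tsv")
truth_shared <- intersect(paste(truth_a$gene1, truth_a$gene2),
                          paste(truth_b$gene1, truth_b$gene2))
got <- paste(shared$gene1, shared$gene2)
cat(sprintf("Ground truth: %d shared differential pairs injected; %d of them recovered\n",
            length(truth_shared), sum(truth_shared %in% got)))
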