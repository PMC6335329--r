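#!/usr/bin/env Rscript
# Stage 1: simulate two blood-methylation case-control "diseases" with known
# co-methylation structure. Both share three differential gene pairs whose
# correlation flips sign between conditions (interval distance >= 3), and
# each has one disease-specific differential pair, so the downstream
# cross-disease intersection has a known answer. Disease A is additionally
# expanded to probe level (3 probes/gene, sd 0.01 noise) to exercise the
# aggregation stage. Sample sizes mirror the RA cohort (354 cases, 335
# controls).

library(comethdiff)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

shared_pairs <- data.frame(
  gene_i = c(1, 3, 5), gene_j = c(2, 4, 6),
  r_control = c(-0.60, -0.55, 0.70), r_case = c(0.40, 0.50, -0.35))

# Correlated modules covering most genes emulate the pervasive block
# structure of real co-methylation data (where the global SD of pairwise r
# is ~0.2-0.26); genes 1-20 stay block-free to host the injected pairs.
make_blocks <- function(rs) {
  lapply(seq_along(rs), function(i) {
    list(genes = (i * 20 + 1):(i * 20 + 20), r_control = rs[i], r_case = rs[i])
  })
}

spec_a <- simulation_spec(
  n_genes = 120, n_case = 354, n_control = 335, seed = 20260101,
  blocks = make_blocks(c(0.5, 0.3, 0.6, 0.4, 0.7)),
  differential_pairs = rbind(
    shared_pairs,
    data.frame(gene_i = 7, gene_j = 8, r_control = -0.50, r_case = 0.45)),
  probes_per_gene = 3L, probe_noise_sd = 0.01)

spec_b <- simulation_spec(
  n_genes = 120, n_case = 335, n_control = 237, seed = 20260102,
  blocks = make_blocks(c(0.4, 0.6, 0.3, 0.5, 0.6)),
  differential_pairs = rbind(
    shared_pairs,
    data.frame(gene_i = 9, gene_j = 10, r_control = 0.60, r_case = -0.40)))

a <- generate_dataset(spec_a)
b <- generate_dataset(spec_b)
probes_a <- expand_to_probes(a$genes, spec_a)

# disease A goes out at probe level (plus annotation); B at gene level
write_beta_matrix(probes_a$probes, file.path(out, "diseaseA_probes.tsv"))
write.table(data.frame(ID = probes_a$map$probe_id,
                       UCSC_RefGene_Name = probes_a$map$gene),
            file.path(out, "diseaseA_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_phenotypes(a$phenotypes, file.path(out, "diseaseA_phenotypes.tsv"))
write_beta_matrix(b$genes, file.path(out, "diseaseB_genes.tsv"))
write_phenotypes(b$phenotypes, file.path(out, "diseaseB_phenotypes.tsv"))
# gene-level truth for disease A too, for the aggregation check in stage 2
write_beta_matrix(a$genes, file.path(out, "diseaseA_genes_truth.tsv"))

for (nm in c("a", "b")) {
  tr <- get(nm)$truth$differential_pairs
  write.table(tr, file.path(out, sprintf("disease%s_truth_pairs.tsv", toupper(nm))),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("Simulated two diseases of 120 genes:\n")
cat("  A:", ncol(a$genes), "samples,", nrow(probes_a$probes), "probes;",
    "B:", ncol(b$genes), "samples (gene level)\n")
cat("  3 shared + 1 disease-specific differential pair(s) each;",
    "target interval distances:\n")
print(a$truth$differential_pairs[, c("gene1", "gene2", "interval_distance_target")])
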