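test_that("generation is seed-deterministic and bounded inside (0, 1)", {
  spec <- simulation_spec(n_genes = 12, n_case = 30, n_control = 25, seed = 7,
                          blocks = list(list(genes = 1:4, r_control = 0.5, r_case = 0.5)))
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_true(all(d1$genes > 0 & d1$genes < 1))
  expect_identical(dim(d1$genes), c(12L, 55L))
  expect_identical(as.integer(table(d1$phenotypes$group)[c("control", "case")]),
                   c(25L, 30L))
})

test_that("the per-gene affine rescale leaves pair correlations untouched", {
  # same seed, different beta ranges: the latent draw is identical, so
  # Pearson correlations must agree to floating precision
  s1 <- simulation_spec(n_genes = 10, n_case = 40, n_control = 40, seed = 19,
                        beta_range = c(0.05, 0.95))
  s2 <- simulation_spec(n_genes = 10, n_case = 40, n_control = 40, seed = 19,
                        beta_range = c(0.3, 0.4))
  d1 <- generate_dataset(s1)
  d2 <- generate_dataset(s2)
  p1 <- all_pairs_correlations(d1$genes, d1$phenotypes)
  p2 <- all_pairs_correlations(d2$genes, d2$phenotypes)
  expect_equal(p1$r_control, p2$r_control, tolerance = 1e-12)
  expect_equal(p1$r_case, p2$r_case, tolerance = 1e-12)
})

test_that("null targets produce near-zero empirical correlation at large n", {
  spec <- simulation_spec(
    n_genes = 2, n_case = 5000, n_control = 5000, seed = 23,
    differential_pairs = data.frame(gene_i = 1, gene_j = 2,
                                    r_control = 0, r_case = 0))
  d <- generate_dataset(spec)
  p <- all_pairs_correlations(d$genes, d$phenotypes)
  bound <- 3.5 / sqrt(5000)  # large-sample convergence bound
  expect_lt(abs(p$r_control), bound)
  expect_lt(abs(p$r_case), bound)
})

test_that("injected differential pairs land at their target interval distance", {
  hits <- vapply(1:25, function(s) {
    spec <- simulation_spec(
      n_genes = 6, n_case = 2000, n_control = 2000, seed = 4000L + s,
      differential_pairs = data.frame(gene_i = 1, gene_j = 2,
                                      r_control = -0.6, r_case = 0.4))
    d <- generate_dataset(spec)
    p <- annotate_pairs(all_pairs_correlations(d$genes, d$phenotypes))
    row <- p[p$gene1 == "g00001" & p$gene2 == "g00002", ]
    expect_identical(d$truth$differential_pairs$interval_distance_target, 4L)
    row$interval_distance
  }, 1L)
  expect_true(all(hits == 4L))  # sampling error ~0.02 at n = 2000, margins >= 0.1
})

test_that("non-PSD targets error by default and are repairable on request", {
  bad <- simulation_spec(
    n_genes = 3, n_case = 20, n_control = 20, seed = 31,
    differential_pairs = data.frame(gene_i = c(1, 1, 2), gene_j = c(2, 3, 3),
                                    r_control = c(0.9, 0.9, -0.9),
                                    r_case = c(0.9, 0.9, -0.9)))
  expect_error(generate_dataset(bad), "positive semi-definite")
  fixed <- generate_dataset(bad, repair_psd = TRUE)
  expect_true(fixed$truth$psd_repaired)
  ev <- eigen(fixed$truth$target_control, symmetric = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(unname(diag(fixed$truth$target_control)), rep(1, 3))
})

test_that("probe expansion inverts aggregation at zero noise", {
  spec <- simulation_spec(n_genes = 5, n_case = 10, n_control = 10, seed = 37,
                          probes_per_gene = 3L, probe_noise_sd = 0)
  d <- generate_dataset(spec)
  ex <- expand_to_probes(d$genes, spec)
  expect_identical(nrow(ex$probes), 15L)
  expect_identical(nrow(ex$map), 15L)
  back <- aggregate_probes_to_genes(ex$probes, ex$map)
  expect_equal(unclass(back$genes), unclass(d$genes), ignore_attr = TRUE)
})

test_that("probe maps are one gene per probe and noise only mildly attenuates", {
  spec2 <- simulation_spec(n_genes = 2, n_case = 10, n_control = 10, seed = 41,
                           probes_per_gene = 2L)
  d2 <- generate_dataset(spec2)
  ex2 <- expand_to_probes(d2$genes, spec2)
  expect_identical(nrow(ex2$map), 4L)
  expect_identical(as.vector(table(ex2$map$gene)), c(2L, 2L))

  spec3 <- simulation_spec(n_genes = 4, n_case = 500, n_control = 500, seed = 43,
                           probes_per_gene = 4L, probe_noise_sd = 0.01)
  d3 <- generate_dataset(spec3)
  ex3 <- expand_to_probes(d3$genes, spec3)
  back <- aggregate_probes_to_genes(ex3$probes, ex3$map)
  for (g in rownames(d3$genes)) {
    expect_gt(pearson(unclass(d3$genes)[g, ], unclass(back$genes)[g, ]), 0.99)
  }
})

test_that("invalid specs are rejected up front", {
  expect_error(simulation_spec(1), "n_genes")
  expect_error(simulation_spec(5, beta_range = c(0, 0.9)), "beta_range")
  expect_error(simulation_spec(5, probe_noise_sd = -1), "probe_noise_sd")
  expect_error(simulation_spec(5, blocks = list(list(genes = 1:9, r_control = 0.5,
                                                     r_case = 0.5))),
               "out of range")
  expect_error(
    simulation_spec(5, differential_pairs = data.frame(gene_i = 1, gene_j = 1,
                                                       r_control = 0, r_case = 0)),
    "gene_i == gene_j")
})
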