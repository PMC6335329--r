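test_that("probe averaging matches a per-cell loop oracle", {
  # 6 probes, 3 genes, 4 samples; one probe maps to two genes
  set.seed(5)
  vals <- matrix(runif(24, 0.1, 0.9), nrow = 6,
                 dimnames = list(sprintf("cg%02d", 1:6), sprintf("s%d", 1:4)))
  probes <- beta_matrix(vals, level = "probe")
  map <- data.frame(
    probe_id = c("cg01", "cg02", "cg03", "cg04", "cg05", "cg05", "cg06"),
    gene = c("A", "A", "B", "B", "B", "C", "C"))
  res <- aggregate_probes_to_genes(probes, map)

  # oracle: explicit loop over gene-sample cells
  genes <- sort(unique(map$gene))
  expected <- matrix(NA_real_, length(genes), 4, dimnames = list(genes, colnames(vals)))
  for (g in genes) {
    pr <- map$probe_id[map$gene == g]
    for (s in colnames(vals)) expected[g, s] <- mean(vals[pr, s])
  }
  expect_equal(unclass(res$genes), expected, ignore_attr = TRUE)
  expect_identical(rownames(res$genes), genes)  # lexicographic order

  # multi-gene probe cg05 contributes identically to B and C
  expect_equal(unclass(res$genes)["C", ], colMeans(vals[c("cg05", "cg06"), ]))

  expect_identical(res$report$n_probes_in, 6L)
  expect_identical(res$report$n_probes_mapped, 6L)
  expect_identical(res$report$n_genes_out, 3L)
  expect_identical(unname(res$report$probes_per_gene), c(2L, 3L, 2L))
})

test_that("single-probe genes pass through and means stay within probe range", {
  vals <- matrix(c(0.2, 0.4, 0.7, 0.1), nrow = 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  probes <- beta_matrix(vals, level = "probe")
  map <- data.frame(probe_id = c("p1", "p2"), gene = c("G", "G"))
  res <- aggregate_probes_to_genes(probes, map)
  expect_equal(unname(unclass(res$genes)["G", ]), c(0.3, 0.4))  # mean of two

  solo <- aggregate_probes_to_genes(probes, data.frame(probe_id = "p1", gene = "G"))
  expect_equal(unname(unclass(solo$genes)["G", ]), unname(vals["p1", ]))

  big <- make_toy_dataset(g = 1)  # reuse generator for a larger random check
  set.seed(9)
  pv <- matrix(runif(40, 0, 1), nrow = 10,
               dimnames = list(sprintf("q%02d", 1:10), sprintf("s%d", 1:4)))
  m2 <- data.frame(probe_id = rownames(pv), gene = rep(c("X", "Y"), each = 5))
  r2 <- aggregate_probes_to_genes(beta_matrix(pv, level = "probe"), m2)
  for (g in c("X", "Y")) {
    pr <- m2$probe_id[m2$gene == g]
    expect_true(all(unclass(r2$genes)[g, ] >= apply(pv[pr, ], 2, min)))
    expect_true(all(unclass(r2$genes)[g, ] <= apply(pv[pr, ], 2, max)))
  }
})

test_that("aggregation is invariant to probe and sample permutations", {
  set.seed(13)
  vals <- matrix(runif(32, 0.1, 0.9), nrow = 8,
                 dimnames = list(sprintf("cg%02d", 1:8), sprintf("s%d", 1:4)))
  map <- data.frame(probe_id = rownames(vals),
                    gene = sample(c("A", "B", "C"), 8, replace = TRUE))
  base <- aggregate_probes_to_genes(beta_matrix(vals, level = "probe"), map)
  perm <- aggregate_probes_to_genes(
    beta_matrix(vals[sample(8), sample(4)], level = "probe"), map)
  expect_equal(unclass(base$genes),
               unclass(perm$genes)[rownames(base$genes), colnames(base$genes)],
               ignore_attr = TRUE)
})

test_that("unmapped probes are dropped silently; empty overlap is an error", {
  vals <- matrix(runif(8, 0.1, 0.9), nrow = 4,
                 dimnames = list(sprintf("cg%02d", 1:4), c("s1", "s2")))
  probes <- beta_matrix(vals, level = "probe")
  map <- data.frame(probe_id = c("cg01", "cg02"), gene = c("A", "A"))
  res <- aggregate_probes_to_genes(probes, map)
  expect_identical(res$report$n_probes_mapped, 2L)
  expect_identical(res$report$n_probes_in, 4L)

  off <- data.frame(probe_id = c("zz1", "zz2"), gene = c("A", "B"))
  expect_error(aggregate_probes_to_genes(probes, off), "no mappable probes")
})

test_that("multi-gene probes can be dropped; missing values follow the declared policy", {
  vals <- matrix(c(0.2, 0.4, 0.6, 0.8), nrow = 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  map <- data.frame(probe_id = c("p1", "p1", "p2"), gene = c("A", "B", "A"))
  res <- aggregate_probes_to_genes(beta_matrix(vals, level = "probe"), map,
                                   multi_gene = "drop")
  expect_identical(rownames(res$genes), "A")  # p1 excluded entirely
  expect_equal(unname(unclass(res$genes)["A", ]), unname(vals["p2", ]))

  nav <- vals
  nav[1, 1] <- NA
  probes_na <- beta_matrix(nav, level = "probe")
  expect_error(aggregate_probes_to_genes(probes_na, map), "missing probe value")
  ok <- aggregate_probes_to_genes(probes_na, map, na_action = "ignore")
  # gene A in s1: only p2 available; in s2: mean of both probes
  expect_equal(unname(unclass(ok$genes)["A", ]), c(0.4, mean(c(0.6, 0.8))))
  # gene B has only p1, which is missing in s1: cell stays missing
  expect_true(is.na(unclass(ok$genes)["B", "s1"]))
  expect_equal(unname(unclass(ok$genes)["B", "s2"]), 0.6)
})
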