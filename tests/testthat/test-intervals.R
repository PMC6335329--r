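test_that("interval assignment follows the half-open convention with a closed top bin", {
  expect_identical(assign_interval(-0.561), 2L)  # strong negative
  expect_identical(assign_interval(0.382), 6L)   # weak positive
  expect_identical(assign_interval(c(-1, -0.75, 0, 0.75, 1)), c(1L, 2L, 5L, 8L, 8L))
  expect_identical(assign_interval(c(-0.25, 0.25, 0.5)), c(4L, 6L, 7L))
  expect_error(assign_interval(1.1), "outside")
  expect_error(assign_interval(NA_real_), "undefined")
  # values within floating tolerance of the edges are clamped
  expect_identical(assign_interval(1 + 1e-13), 8L)
  expect_identical(assign_interval(-1 - 1e-13), 1L)
})

test_that("interval distance is the absolute bin difference", {
  expect_identical(interval_distance(2, 6), 4L)  # strong neg -> weak pos
  expect_identical(interval_distance(8, 3), 5L)  # strongest pos -> weak neg
  expect_identical(interval_distance(1:8, 1:8), rep(0L, 8))
  expect_error(interval_distance(0, 3), "1\\.\\.8")
  expect_error(interval_distance(2, 9), "1\\.\\.8")
})

test_that("transition counts match a naive double-loop oracle and conserve pairs", {
  pairs <- make_random_pairs(1000, seed = 19, na_frac = 0.03)
  tm <- build_transition_matrix(pairs)
  oracle <- oracle_transition_counts(pairs)
  expect_equal(unname(tm$counts), oracle$counts)
  expect_identical(as.integer(tm$n_excluded), oracle$excluded)
  expect_equal(sum(tm$counts) + tm$n_excluded, nrow(pairs))

  # row percentages sum to 100 on non-empty rows, full precision
  rs <- rowSums(tm$counts)
  sums <- rowSums(tm$row_percentages)[rs > 0]
  expect_equal(unname(sums), rep(100, sum(rs > 0)), tolerance = 1e-6)

  conc <- data.frame(gene1 = sprintf("a%d", 1:5), gene2 = sprintf("b%d", 1:5),
                     r_control = rep(0.9, 5), r_case = rep(0.9, 5))
  tmc <- build_transition_matrix(conc)
  expect_equal(unname(tmc$counts[8, 8]), 5)
  expect_equal(sum(tmc$counts), 5)
})

test_that("min-distance and exact-distance counts satisfy their lattice identities", {
  pairs <- make_random_pairs(2000, seed = 23, na_frac = 0.01)
  tm <- build_transition_matrix(pairs)
  expect_equal(count_by_min_distance(tm, 0), sum(tm$counts))
  for (k in 0:7) {
    expect_equal(count_by_min_distance(tm, k),
                 sum(vapply(k:7, function(j) count_by_exact_distance(tm, j), 0)))
  }
  mins <- vapply(0:7, function(k) count_by_min_distance(tm, k), 0)
  expect_true(all(diff(mins) <= 0))  # non-increasing in k
  expect_error(count_by_min_distance(tm, 8), "0\\.\\.7")
})

test_that("large-change extraction equals the loop-oracle selection", {
  pairs <- make_random_pairs(500, seed = 29, na_frac = 0.02)
  for (md in c(1L, 3L, 5L)) {
    got <- extract_large_change_pairs(pairs, min_distance = md)
    ann <- annotate_pairs(pairs)
    keep <- !is.na(ann$interval_distance) & ann$interval_distance >= md
    oracle <- ann[keep, ]
    oracle <- oracle[order(oracle$gene1, oracle$gene2, method = "radix"), ]
    expect_identical(got$gene1, oracle$gene1)
    expect_identical(got$gene2, oracle$gene2)
    expect_equal(got$delta, oracle$delta)
    # cardinality matches the transition-matrix count
    expect_equal(nrow(got), count_by_min_distance(build_transition_matrix(pairs), md))
  }
  expect_error(extract_large_change_pairs(pairs, min_distance = 0), "1\\.\\.7")
})

test_that("single pairs are included or excluded per their interval distance", {
  p <- data.frame(gene1 = "ARHGAP17", gene2 = "TSHZ3",
                  r_control = -0.561, r_case = 0.382)
  expect_identical(nrow(extract_large_change_pairs(p, min_distance = 3)), 1L)
  expect_identical(nrow(extract_large_change_pairs(p, min_distance = 4)), 1L)
  expect_identical(nrow(extract_large_change_pairs(p, min_distance = 5)), 0L)
  same_bin <- data.frame(gene1 = "A", gene2 = "B", r_control = 0.10, r_case = 0.20)
  expect_identical(nrow(extract_large_change_pairs(same_bin, min_distance = 1)), 0L)
})

test_that("the delta filter is strict and reports boundary ties", {
  p <- data.frame(
    gene1 = c("ARHGAP17", "A", "CDK20"),
    gene2 = c("TSHZ3", "B", "PLEKHF2"),
    r_control = c(-0.561, 0.1, -0.342),
    r_case = c(0.382, 0.2, 0.458))
  got <- suppressMessages(filter_by_delta(p, 0.8))
  expect_identical(got$gene1, "ARHGAP17")        # |0.943| kept
  expect_identical(attr(got, "n_boundary"), 1L)  # |0.800| tie excluded
  all_moved <- suppressMessages(filter_by_delta(p, 0))
  expect_identical(nrow(all_moved), 3L)          # every delta != 0 kept
  expect_error(filter_by_delta(p, -1), ">= 0")
})

test_that("custom interval schemes are validated and usable", {
  sc <- interval_scheme(edges = c(-1, 0, 1), labels = c("neg", "pos"))
  expect_identical(assign_interval(c(-0.5, 0.5, 1), sc), c(1L, 2L, 2L))
  expect_error(interval_scheme(edges = c(0, 0, 1)), "strictly increasing")
  expect_error(interval_scheme(edges = c(-1, 0, 1), labels = "x"), "one label per bin")
  expect_identical(interval_scheme()$labels[1], "strongest negative correlation")
})
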