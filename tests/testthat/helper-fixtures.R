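# Shared fixtures and independent oracles, all built in code at test time.

# Random beta matrix (genes x samples) with case/control phenotypes.
make_toy_dataset <- function(g = 10L, n_control = 8L, n_case = 8L, seed = 42L) {
  set.seed(seed)
  vals <- matrix(runif(g * (n_control + n_case), 0.05, 0.95), nrow = g)
  rownames(vals) <- sprintf("g%03d", seq_len(g))
  colnames(vals) <- c(sprintf("c%03d", seq_len(n_control)),
                      sprintf("t%03d", seq_len(n_case)))
  list(
    genes = beta_matrix(vals, level = "gene"),
    phenotypes = phenotype_table(colnames(vals),
                                 rep(c("control", "case"), c(n_control, n_case)))
  )
}

# Scalar per-pair oracle for the all-pairs engine, using stats::cor as the
# independent implementation.
oracle_pair_table <- function(genes, phenotypes) {
  ids <- sort(rownames(genes), method = "radix")
  cs <- phenotypes$sample_id[phenotypes$group == "control"]
  ts <- phenotypes$sample_id[phenotypes$group == "case"]
  rows <- list()
  k <- 0L
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      rc <- suppressWarnings(stats::cor(genes[ids[i], cs], genes[ids[j], cs]))
      ra <- suppressWarnings(stats::cor(genes[ids[i], ts], genes[ids[j], ts]))
      k <- k + 1L
      rows[[k]] <- data.frame(gene1 = ids[i], gene2 = ids[j],
                              r_control = rc, r_case = ra,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$r_control[is.nan(out$r_control)] <- NA_real_
  out$r_case[is.nan(out$r_case)] <- NA_real_
  out
}

# Naive double-loop transition-count oracle.
oracle_transition_counts <- function(pairs, edges = seq(-1, 1, by = 0.25)) {
  nb <- length(edges) - 1L
  counts <- matrix(0, nb, nb)
  excluded <- 0L
  bin1 <- function(r) {
    for (b in seq_len(nb)) {
      hi_ok <- if (b == nb) r <= edges[b + 1L] else r < edges[b + 1L]
      if (r >= edges[b] && hi_ok) return(b)
    }
    stop("unbinnable value ", r)
  }
  for (k in seq_len(nrow(pairs))) {
    rc <- pairs$r_control[k]
    ra <- pairs$r_case[k]
    if (is.na(rc) || is.na(ra)) {
      excluded <- excluded + 1L
    } else {
      counts[bin1(rc), bin1(ra)] <- counts[bin1(rc), bin1(ra)] + 1
    }
  }
  list(counts = counts, excluded = excluded)
}

# Random pair-correlation table over a synthetic gene universe.
make_random_pairs <- function(n, n_genes = 300L, seed = 1L, na_frac = 0) {
  set.seed(seed)
  ids <- sprintf("G%04d", seq_len(n_genes))
  i <- sample(n_genes, n, replace = TRUE)
  j <- sample(n_genes - 1L, n, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)
  g1 <- pmin(ids[i], ids[j])
  g2 <- pmax(ids[i], ids[j])
  key <- paste(g1, g2)
  keep <- !duplicated(key)
  out <- data.frame(gene1 = g1[keep], gene2 = g2[keep],
                    r_control = runif(sum(keep), -1, 1),
                    r_case = runif(sum(keep), -1, 1),
                    stringsAsFactors = FALSE)
  if (na_frac > 0) {
    nna <- ceiling(na_frac * nrow(out))
    out$r_control[sample(nrow(out), nna)] <- NA_real_
    out$r_case[sample(nrow(out), nna)] <- NA_real_
  }
  out
}
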