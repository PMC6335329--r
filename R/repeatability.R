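#' Configuration for the subsampling repeatability experiment
#'
#' Defaults mirror the design used to assess how many samples are needed for
#' stable co-methylation estimates: five disjoint groups of 100 genes and
#' replicate sample sizes spanning 2 to 150.
#'
#' @param n_groups number of disjoint gene groups.
#' @param group_size genes per group (`>= 2`).
#' @param sample_sizes replicate sizes; each `n` needs `2 n` samples in the
#'   chosen condition.
#' @param seed master seed; per-(group, size) substreams are derived from it
#'   so curves are reproducible and order-independent.
#' @return a `repeatability_config` list.
#' @export
repeatability_config <- function(n_groups = 5L, group_size = 100L,
                                 sample_sizes = c(2L, seq(5L, 150L, by = 5L)),
                                 seed = 1L) {
  if (group_size < 2L) stop("group_size must be >= 2")
  if (n_groups < 1L) stop("n_groups must be >= 1")
  if (any(sample_sizes < 2L)) stop("every sample size must be >= 2")
  structure(list(n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 sample_sizes = as.integer(sample_sizes),
                 seed = as.integer(seed)),
            class = "repeatability_config")
}

# Deterministic substream seed per (group, sample size), kept below 2^31.
substream_seed <- function(master, g, n) {
  as.integer((as.numeric(master) * 10007 + g * 1009 + n * 7) %% 2147483629)
}

#' Subsampling repeatability of pair correlations
#'
#' For each of `n_groups` disjoint gene groups (drawn without replacement
#' from the gene universe) and each sample size `n`: draw `n` samples of the
#' chosen condition without replacement, draw a second, disjoint set of `n`
#' samples from the remainder, compute all `C(group_size, 2)` pair
#' correlations in each replicate, and record the agreement — the Pearson
#' correlation between the two replicates' pair-correlation vectors
#' (undefined entries dropped pairwise and counted). Rising agreement with
#' `n` indicates the co-methylation estimates are repeatable at that scale.
#'
#' @param genes gene-level beta matrix.
#' @param phenotypes phenotype table.
#' @param group `"case"` or `"control"`: the condition to subsample.
#' @param cfg a [repeatability_config()].
#' @return data.frame with one row per (group, n): columns `group`, `n`,
#'   `agreement` (`NA` when degenerate, e.g. a constant replicate vector),
#'   `n_pairs_used` (defined in both replicates).
#' @export
run_repeatability <- function(genes, phenotypes, group = c("case", "control"),
                              cfg = repeatability_config()) {
  group <- match.arg(group)
  sid <- group_samples(genes, phenotypes, group)
  n_avail <- length(sid)
  bad_n <- cfg$sample_sizes[2L * cfg$sample_sizes > n_avail]
  if (length(bad_n)) {
    stop("sample size ", bad_n[1L], " needs ", 2L * bad_n[1L],
         " samples but condition '", group, "' has only ", n_avail)
  }
  if (cfg$n_groups * cfg$group_size > nrow(genes)) {
    stop("need ", cfg$n_groups * cfg$group_size, " genes for ",
         cfg$n_groups, " disjoint groups of ", cfg$group_size,
         ", but matrix has ", nrow(genes))
  }

  set.seed(cfg$seed)
  pool <- resample(rownames(genes), cfg$n_groups * cfg$group_size)
  groups <- split(pool, rep(seq_len(cfg$n_groups), each = cfg$group_size))

  rows <- vector("list", cfg$n_groups * length(cfg$sample_sizes))
  k <- 0L
  for (g in seq_len(cfg$n_groups)) {
    sub <- unclass(genes)[groups[[g]], sid, drop = FALSE]
    for (n in cfg$sample_sizes) {
      set.seed(substream_seed(cfg$seed, g, n))
      s1 <- resample(seq_len(n_avail), n)
      s2 <- resample(setdiff(seq_len(n_avail), s1), n)
      stopifnot(length(intersect(s1, s2)) == 0L)
      v1 <- pair_cor_vector(sub[, s1, drop = FALSE])
      v2 <- pair_cor_vector(sub[, s2, drop = FALSE])
      ok <- !is.na(v1) & !is.na(v2)
      agree <- if (sum(ok) >= 2L) pearson(v1[ok], v2[ok]) else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(group = g, n = n, agreement = agree,
                              n_pairs_used = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
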