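#' Specification for a synthetic two-condition beta-value dataset
#'
#' Describes a gene-level methylation dataset for a case and a control
#' condition with controlled pairwise Pearson correlation structure:
#' optional correlated blocks (per-condition within-block correlation) and
#' injected differential pairs whose correlation differs between the
#' conditions. Default sample sizes match a large blood-methylation
#' case-control cohort (354 cases, 335 controls).
#'
#' @param n_genes number of genes.
#' @param n_case,n_control samples per condition.
#' @param blocks list of blocks, each `list(genes = <indices>, r_control =,
#'   r_case =)` giving the common within-block correlation per condition.
#' @param differential_pairs data.frame with columns `gene_i`, `gene_j`
#'   (indices), `r_control`, `r_case`: pairwise correlation targets that
#'   differ between conditions. By default placed on otherwise-independent
#'   genes; overlapping blocks and pairs are allowed but must leave the
#'   assembled target positive semi-definite.
#' @param probes_per_gene probes simulated per gene by [expand_to_probes()].
#' @param probe_noise_sd SD of the independent Gaussian probe noise.
#' @param beta_range `(lo, hi)` with `0 < lo < hi < 1`: each gene's values
#'   are mapped into this range.
#' @param seed integer seed; generation is fully reproducible.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes, n_case = 354L, n_control = 335L,
                            blocks = list(), differential_pairs = NULL,
                            probes_per_gene = 1L, probe_noise_sd = 0.01,
                            beta_range = c(0.05, 0.95), seed = 1L) {
  if (n_genes < 2L) stop("n_genes must be >= 2")
  if (n_case < 2L || n_control < 2L) stop("each condition needs >= 2 samples")
  if (beta_range[1L] <= 0 || beta_range[2L] >= 1 || beta_range[1L] >= beta_range[2L]) {
    stop("beta_range must satisfy 0 < lo < hi < 1")
  }
  if (probe_noise_sd < 0) stop("probe_noise_sd must be >= 0")
  for (b in blocks) {
    if (!all(c("genes", "r_control", "r_case") %in% names(b))) {
      stop("each block needs fields genes, r_control, r_case")
    }
    if (any(b$genes < 1L | b$genes > n_genes)) stop("block gene index out of range")
  }
  if (!is.null(differential_pairs)) {
    need <- c("gene_i", "gene_j", "r_control", "r_case")
    if (!all(need %in% names(differential_pairs))) {
      stop("differential_pairs needs columns: ", paste(need, collapse = ", "))
    }
    with(differential_pairs, {
      if (any(gene_i == gene_j)) stop("differential pair with gene_i == gene_j")
      if (any(abs(c(r_control, r_case)) > 1)) stop("pair correlation target outside [-1, 1]")
    })
  }
  structure(list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
                 n_control = as.integer(n_control), blocks = blocks,
                 differential_pairs = differential_pairs,
                 probes_per_gene = as.integer(probes_per_gene),
                 probe_noise_sd = probe_noise_sd,
                 beta_range = as.numeric(beta_range), seed = as.integer(seed)),
            class = "simulation_spec")
}

# Assemble the per-condition target correlation matrix from blocks and pairs.
assemble_target <- function(spec, condition = c("control", "case")) {
  condition <- match.arg(condition)
  fld <- paste0("r_", condition)
  R <- diag(spec$n_genes)
  for (b in spec$blocks) {
    idx <- b$genes
    R[idx, idx] <- b[[fld]]
    diag(R)[idx] <- 1
  }
  dp <- spec$differential_pairs
  if (!is.null(dp)) {
    for (k in seq_len(nrow(dp))) {
      i <- dp$gene_i[k]
      j <- dp$gene_j[k]
      R[i, j] <- R[j, i] <- dp[[fld]][k]
    }
  }
  R
}

# Validate positive semi-definiteness; optionally repair by eigenvalue
# clipping at 1e-10 followed by re-normalization to unit diagonal.
ensure_psd <- function(R, repair = FALSE, tol = 1e-8) {
  ev <- eigen(R, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) >= -tol) return(list(R = R, repaired = FALSE, min_eigenvalue = min(lam)))
  if (!repair) {
    stop(sprintf(
      "target correlation matrix is not positive semi-definite (min eigenvalue %.3e); set repair_psd = TRUE to clip",
      min(lam)))
  }
  lam2 <- pmax(lam, 1e-10)
  R2 <- ev$vectors %*% (lam2 * t(ev$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  list(R = R2, repaired = TRUE, min_eigenvalue = min(lam))
}

# Symmetric PSD square root via eigendecomposition (tolerates semidefinite
# targets where Cholesky would fail).
psd_sqrt <- function(R) {
  ev <- eigen(R, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

# Map each row (gene) of a matrix into (lo, hi) by an increasing affine map
# (min-max rescale). Increasing affine maps preserve sample Pearson
# correlations exactly. Constant rows map to the range midpoint.
rescale_rows <- function(x, lo, hi) {
  mn <- apply(x, 1L, min)
  mx <- apply(x, 1L, max)
  rng <- mx - mn
  flat <- rng == 0
  rng[flat] <- 1
  out <- lo + (x - mn) / rng * (hi - lo)
  out[flat, ] <- (lo + hi) / 2
  out
}

#' Generate a synthetic two-condition gene-level beta dataset
#'
#' Per condition, samples are drawn from a multivariate normal with the
#' assembled target correlation matrix, then each gene's values are mapped
#' into `beta_range` by a per-gene increasing affine (min-max) rescale,
#' which preserves sample Pearson correlations exactly. All emitted values
#' lie strictly inside `(0, 1)`. Identical specs give bit-identical output.
#'
#' @param spec a [simulation_spec()].
#' @param repair_psd repair a non-PSD assembled target by eigenvalue
#'   clipping (logged and reflected in the returned truth) instead of
#'   failing.
#' @return list with `genes` (gene-level beta matrix, genes x samples),
#'   `phenotypes` (phenotype table), and `truth`: the per-condition target
#'   correlation matrices actually used, the differential pairs annotated
#'   with their target bins/interval distance, and whether a PSD repair was
#'   applied.
#' @export
generate_dataset <- function(spec, repair_psd = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  Rc <- ensure_psd(assemble_target(spec, "control"), repair = repair_psd)
  Ra <- ensure_psd(assemble_target(spec, "case"), repair = repair_psd)

  gene_ids <- sprintf("g%05d", seq_len(spec$n_genes))
  set.seed(spec$seed)
  draw <- function(R, n) {
    z <- matrix(rnorm(n * nrow(R)), n, nrow(R))
    t(z %*% psd_sqrt(R))   # genes x samples
  }
  ctrl <- draw(Rc$R, spec$n_control)
  case <- draw(Ra$R, spec$n_case)
  vals <- cbind(ctrl, case)
  vals <- rescale_rows(vals, spec$beta_range[1L], spec$beta_range[2L])
  sample_ids <- c(sprintf("control_%03d", seq_len(spec$n_control)),
                  sprintf("case_%03d", seq_len(spec$n_case)))
  dimnames(vals) <- list(gene_ids, sample_ids)
  phen <- phenotype_table(sample_ids,
                          rep(c("control", "case"),
                              c(spec$n_control, spec$n_case)))

  truth_pairs <- NULL
  dp <- spec$differential_pairs
  if (!is.null(dp)) {
    bc <- assign_interval(dp$r_control)
    ba <- assign_interval(dp$r_case)
    truth_pairs <- data.frame(
      gene1 = pmin(gene_ids[dp$gene_i], gene_ids[dp$gene_j]),
      gene2 = pmax(gene_ids[dp$gene_i], gene_ids[dp$gene_j]),
      r_control_target = dp$r_control,
      r_case_target = dp$r_case,
      bin_control_target = bc,
      bin_case_target = ba,
      interval_distance_target = abs(ba - bc),
      stringsAsFactors = FALSE
    )
  }
  list(
    genes = beta_matrix(vals, level = "gene"),
    phenotypes = phen,
    truth = list(
      target_control = Rc$R, target_case = Ra$R,
      differential_pairs = truth_pairs,
      psd_repaired = Rc$repaired || Ra$repaired
    )
  )
}

#' Expand a gene-level matrix to synthetic probes
#'
#' Each gene yields `probes_per_gene` probes equal to the gene value plus
#' independent Gaussian noise (`probe_noise_sd`), clipped to `[0, 1]`, with
#' a companion probe-to-gene map. With zero noise, aggregation by
#' [aggregate_probes_to_genes()] recovers the gene matrix exactly.
#'
#' @param genes gene-level beta matrix.
#' @param spec a [simulation_spec()] providing `probes_per_gene`,
#'   `probe_noise_sd` and the seed for the noise substream.
#' @return list with `probes` (probe-level beta matrix) and `map`
#'   (data.frame `probe_id`, `gene`).
#' @export
expand_to_probes <- function(genes, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  k <- spec$probes_per_gene
  ids <- rownames(genes)
  probe_ids <- paste0(rep(ids, each = k), "_p", rep(seq_len(k), times = length(ids)))
  vals <- unclass(genes)[rep(seq_along(ids), each = k), , drop = FALSE]
  set.seed(substream_seed(spec$seed, 0L, 1L))
  if (spec$probe_noise_sd > 0) {
    vals <- vals + rnorm(length(vals), sd = spec$probe_noise_sd)
    vals <- pmin(pmax(vals, 0), 1)
  }
  rownames(vals) <- probe_ids
  list(
    probes = beta_matrix(vals, level = "probe"),
    map = data.frame(probe_id = probe_ids, gene = rep(ids, each = k),
                     stringsAsFactors = FALSE)
  )
}
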