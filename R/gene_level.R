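#' Collapse probe-level beta values to gene level by averaging
#'
#' Each gene's methylation value in a sample is the arithmetic mean of the
#' beta values of all probes annotated to that gene. Probes absent from the
#' annotation are dropped (and counted); probes annotated to several genes
#' contribute to every listed gene by default. Output genes are in
#' lexicographic (C-locale) order, and mean values stay within `[0, 1]`.
#'
#' Missing-value policy: with `na_action = "fail"` (the default) any missing
#' probe value among the mapped probes aborts with a count of offending
#' cells, keeping downstream pair counts well-defined. With
#' `na_action = "ignore"` the mean is taken over the available probe values
#' per sample, and a gene-sample cell with no available probes is `NA`.
#'
#' @param probes probe-level beta matrix (features x samples).
#' @param map probe-to-gene annotation as returned by
#'   [read_probe_annotation()]: columns `probe_id`, `gene`.
#' @param multi_gene `"all"` (multi-gene probes feed every listed gene) or
#'   `"drop"` (exclude probes annotated to more than one gene).
#' @param na_action `"fail"` or `"ignore"`; see Details.
#' @return list with `genes` (gene-level beta matrix) and `report`, a
#'   [GeneAggregationReport]-style list: `n_probes_in`, `n_probes_mapped`,
#'   `n_genes_out`, `probes_per_gene` (named integer vector).
#' @export
aggregate_probes_to_genes <- function(probes, map,
                                      multi_gene = c("all", "drop"),
                                      na_action = c("fail", "ignore")) {
  multi_gene <- match.arg(multi_gene)
  na_action <- match.arg(na_action)
  if (!all(c("probe_id", "gene") %in% names(map))) {
    stop("map must have columns probe_id and gene")
  }
  if (multi_gene == "drop") {
    n_per_probe <- table(map$probe_id)
    keep <- names(n_per_probe)[n_per_probe == 1L]
    map <- map[map$probe_id %in% keep, , drop = FALSE]
  }
  map <- map[map$probe_id %in% rownames(probes), , drop = FALSE]
  if (nrow(map) == 0L) stop("no mappable probes: annotation and matrix share no probe ids")

  vals <- unclass(probes)[map$probe_id, , drop = FALSE]
  nav <- is.na(vals)
  if (na_action == "fail" && any(nav)) {
    stop(sum(nav), " missing probe value(s) among mapped probes; ",
         "use na_action = 'ignore' to average over available probes")
  }
  vals[nav] <- 0
  sums <- rowsum(vals, group = map$gene)
  cnts <- rowsum((!nav) + 0, group = map$gene)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out <- out[order_c(rownames(out)), , drop = FALSE]

  report <- list(
    n_probes_in = nrow(probes),
    n_probes_mapped = length(unique(map$probe_id)),
    n_genes_out = nrow(out),
    probes_per_gene = vapply(split(map$probe_id, map$gene), length, 1L)[rownames(out)]
  )
  list(genes = beta_matrix(out, level = "gene"), report = report)
}
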