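#' Run the full two-disease differential co-methylation pipeline
#'
#' Composes the stages end to end for two diseases: (optional) probe-to-gene
#' aggregation, all-pairs case/control correlations, transition matrix
#' (counts and row percentages), large-change extraction, cross-disease
#' intersection, delta filtering and unique-gene export. Every table is
#' written under `out_dir` and a JSON manifest records parameters and the
#' row/exclusion counts of every output.
#'
#' @param diseases named list of exactly two entries, each
#'   `list(genes = <gene-level beta matrix>, phenotypes = <phenotype table>)`
#'   or `list(probes = <probe-level matrix>, map = <probe-gene map>,
#'   phenotypes = ...)` (aggregated on the fly).
#' @param out_dir output directory (created if missing).
#' @param min_distance minimum interval distance for a large-change pair.
#' @param delta_threshold strict cutoff on `|r_case - r_control|` for the
#'   delta-filtered shared set.
#' @param chunk_size row-block size of the correlation engine.
#' @param scheme an [interval_scheme()].
#' @return invisibly, a list with the in-memory results per disease
#'   (`pairs`, `tm`, `large`, `summary_case`, `summary_control`), the shared
#'   tables, the unique gene list, and the manifest.
#' @export
run_full_pipeline <- function(diseases, out_dir, min_distance = 3L,
                              delta_threshold = 0.8, chunk_size = 512L,
                              scheme = interval_scheme()) {
  if (length(diseases) != 2L || is.null(names(diseases))) {
    stop("`diseases` must be a named list of exactly two diseases")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("comethdiff")),
    parameters = list(min_distance = min_distance,
                      delta_threshold = delta_threshold,
                      chunk_size = chunk_size),
    diseases = list()
  )

  per_disease <- lapply(names(diseases), function(nm) {
    d <- diseases[[nm]]
    if (is.null(d$genes)) {
      if (is.null(d$probes) || is.null(d$map)) {
        stop("disease '", nm, "' needs either `genes` or `probes` + `map`")
      }
      agg <- aggregate_probes_to_genes(d$probes, d$map)
      d$genes <- agg$genes
      manifest$diseases[[nm]]$aggregation <<- agg$report[
        c("n_probes_in", "n_probes_mapped", "n_genes_out")]
    }
    pairs <- all_pairs_correlations(d$genes, d$phenotypes, chunk_size = chunk_size)
    pairs <- annotate_pairs(pairs, scheme)
    tm <- build_transition_matrix(pairs, scheme)
    large <- extract_large_change_pairs(pairs, scheme, min_distance = min_distance)
    sum_ctrl <- summarize_distribution(pairs$r_control)
    sum_case <- summarize_distribution(pairs$r_case)

    write_pair_table(pairs, file.path(out_dir, paste0(nm, "_pairs.tsv")), scheme)
    write_transition_matrix(
      tm,
      file.path(out_dir, paste0(nm, "_transition_counts.tsv")),
      file.path(out_dir, paste0(nm, "_transition_percentages.tsv")))
    write_pair_table(large, file.path(out_dir, paste0(nm, "_large_change.tsv")), scheme)

    manifest$diseases[[nm]] <<- c(manifest$diseases[[nm]], list(
      n_genes = nrow(d$genes),
      n_samples = ncol(d$genes),
      n_pairs = nrow(pairs),
      n_undefined = tm$n_excluded,
      n_large_change = nrow(large),
      mean_r_case = sum_case$mean_r, sd_r_case = sum_case$sd_r,
      mean_r_control = sum_ctrl$mean_r, sd_r_control = sum_ctrl$sd_r
    ))
    stopifnot(sum(tm$counts) + tm$n_excluded == nrow(pairs))
    list(pairs = pairs, tm = tm, large = large,
         summary_case = sum_case, summary_control = sum_ctrl)
  })
  names(per_disease) <- names(diseases)

  shared <- intersect_pairs(per_disease[[1L]]$large, per_disease[[2L]]$large)
  shared_a <- per_disease[[1L]]$large
  shared_key <- paste(shared$gene1, shared$gene2, sep = "\x1f")
  large_a_shared <- shared_a[paste(shared_a$gene1, shared_a$gene2, sep = "\x1f")
                             %in% shared_key, , drop = FALSE]
  shared_b <- per_disease[[2L]]$large
  large_b_shared <- shared_b[paste(shared_b$gene1, shared_b$gene2, sep = "\x1f")
                             %in% shared_key, , drop = FALSE]
  delta_a <- filter_by_delta(large_a_shared, delta_threshold, scheme)
  delta_b <- filter_by_delta(large_b_shared, delta_threshold, scheme)
  shared_delta <- intersect_pairs(delta_a, delta_b)
  genes_shared <- unique_genes(shared)

  write.table(shared, file.path(out_dir, "shared_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(shared_delta, file.path(out_dir, "shared_pairs_delta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_list(genes_shared, file.path(out_dir, "shared_unique_genes.txt"))

  manifest$shared <- list(
    n_shared = nrow(shared),
    n_shared_delta = nrow(shared_delta),
    n_unique_genes = length(genes_shared)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(c(per_disease, list(
    shared = shared, shared_delta = shared_delta,
    unique_genes = genes_shared, manifest = manifest
  )))
}
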