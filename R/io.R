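#' Read a beta-value matrix from TSV
#'
#' Reads either a plain tab-separated table (header row of sample ids, one
#' feature per row, feature id in the first column) or the GEO
#' series-matrix dialect, where metadata lines are prefixed with `!` and the
#' expression table sits between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` sentinels.
#'
#' Cells equal to `NA` or empty are read as missing. Any other non-numeric
#' cell is a parse error naming its location; values outside `[0, 1]` by
#' more than `tol` are a validation error.
#'
#' @param path file path.
#' @param dialect `"plain_tsv"` or `"series_matrix"`.
#' @param level feature level of the rows (`"gene"` or `"probe"`).
#' @param tol out-of-range tolerance passed to [beta_matrix()].
#' @return a validated beta matrix (see [beta_matrix()]).
#' @export
read_beta_matrix <- function(path, dialect = c("plain_tsv", "series_matrix"),
                             level = c("gene", "probe"), tol = 1e-9) {
  dialect <- match.arg(dialect)
  level <- match.arg(level)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "series_matrix") {
    lines <- readLines(path, warn = FALSE)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
      stop("malformed series-matrix file: table sentinels not found in ", path)
    }
    body <- lines[(beg + 1L):(end - 1L)]
    body <- body[!startsWith(body, "!")]
    dt <- fread(text = paste(body, collapse = "\n"), sep = "\t",
                header = TRUE, colClasses = "character", quote = "\"",
                data.table = FALSE)
  } else {
    dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
                data.table = FALSE)
  }
  if (ncol(dt) < 2L) stop("beta matrix table needs a feature id column plus >=1 sample column")
  fid <- gsub('^"|"$', "", dt[[1L]])
  sid <- gsub('^"|"$', "", names(dt)[-1L])
  vals <- matrix(NA_real_, nrow = nrow(dt), ncol = ncol(dt) - 1L,
                 dimnames = list(fid, sid))
  for (j in seq_along(sid)) {
    raw <- trimws(dt[[j + 1L]])
    miss <- is.na(raw) | raw == "" | raw == "NA" | raw == "null"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                   raw[bad[1]], fid[bad[1]], sid[j]))
    }
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  beta_matrix(vals, level = level, tol = tol)
}

#' Write a beta matrix as plain TSV
#'
#' @param beta a beta matrix.
#' @param path output path.
#' @param id_col name of the feature id column in the header.
#' @export
write_beta_matrix <- function(beta, path, id_col = "ID") {
  df <- data.frame(rownames(beta), format_num(unclass(beta)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(beta))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample phenotype table
#'
#' Expects a tab-separated file with a header and columns `sample_id` and
#' `group` (matched case-insensitively; otherwise the first two columns are
#' used). Group tokens must match `case`/`control` case-insensitively.
#'
#' @param path file path.
#' @return a validated phenotype table (see [phenotype_table()]).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              data.table = FALSE)
  nm <- tolower(names(dt))
  si <- match("sample_id", nm)
  gi <- match("group", nm)
  if (is.na(si) || is.na(gi)) {
    if (ncol(dt) < 2L) stop("phenotype table needs columns sample_id and group")
    si <- 1L
    gi <- 2L
  }
  phenotype_table(dt[[si]], dt[[gi]])
}

#' Write a phenotype table as TSV
#' @param phenotypes a phenotype table.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(
    data.frame(sample_id = phenotypes$sample_id,
               group = as.character(phenotypes$group)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Reads a GPL13534-style annotation TSV with a probe id column and a gene
#' symbol column in which multi-gene cells are `;`-delimited (e.g.
#' `"TP53;TP53;WRAP53"`). Symbol lists are split, trimmed and de-duplicated
#' per probe; probes with an empty gene field are dropped and counted.
#'
#' @param path file path.
#' @param probe_col probe id column name (default `"ID"`).
#' @param gene_col gene symbol column name; if `NULL`, the first of
#'   `UCSC_RefGene_Name`, `GENE_SYMBOL`, `gene`, `gene_symbol` present is
#'   used, else the second column.
#' @return data.frame with columns `probe_id`, `gene` (one row per
#'   probe-gene link) and attribute `n_unmapped` counting dropped probes.
#' @export
read_probe_annotation <- function(path, probe_col = "ID", gene_col = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              data.table = FALSE)
  if (!probe_col %in% names(dt)) {
    stop("annotation table lacks probe id column '", probe_col, "'")
  }
  if (is.null(gene_col)) {
    cand <- c("UCSC_RefGene_Name", "GENE_SYMBOL", "gene", "gene_symbol")
    gene_col <- cand[cand %in% names(dt)][1]
    if (is.na(gene_col)) {
      if (ncol(dt) < 2L) stop("annotation table lacks a gene symbol column")
      gene_col <- names(dt)[2L]
    }
  } else if (!gene_col %in% names(dt)) {
    stop("annotation table lacks gene symbol column '", gene_col, "'")
  }
  probes <- dt[[probe_col]]
  if (anyDuplicated(probes)) {
    stop("duplicated probe ids in annotation: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  genes <- lapply(strsplit(dt[[gene_col]], ";", fixed = TRUE), function(g) {
    g <- trimws(g)
    unique(g[!is.na(g) & g != ""])
  })
  n_genes <- lengths(genes)
  n_unmapped <- sum(n_genes == 0L)
  keep <- n_genes > 0L
  map <- data.frame(
    probe_id = rep(probes[keep], n_genes[keep]),
    gene = unlist(genes[keep], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (n_unmapped > 0L) {
    message(n_unmapped, " probe(s) with empty gene field dropped from annotation")
  }
  attr(map, "n_unmapped") <- n_unmapped
  map
}

# Full-precision numeric formatting so write/read round-trips are exact.
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  dim(out) <- dim(x)
  out
}

#' Write a pair-correlation table as TSV
#'
#' Writes the fixed eight-column pair format: `gene1`, `gene2`,
#' `r_control`, `r_case`, `bin_control`, `bin_case`, `interval_distance`,
#' `delta`. Tables lacking the annotation columns are annotated on the fly
#' with `scheme`. Numerics are written in full precision so
#' `read_pair_table(write_pair_table(x))` reproduces `x` exactly.
#'
#' @param pairs a pair table (see [all_pairs_correlations()] or
#'   [extract_large_change_pairs()]).
#' @param path output path.
#' @param scheme interval scheme used when annotation is missing.
#' @export
write_pair_table <- function(pairs, path, scheme = interval_scheme()) {
  pairs <- annotate_pairs(pairs, scheme)
  out <- data.frame(
    gene1 = pairs$gene1,
    gene2 = pairs$gene2,
    r_control = format_num(pairs$r_control),
    r_case = format_num(pairs$r_case),
    bin_control = pairs$bin_control,
    bin_case = pairs$bin_case,
    interval_distance = pairs$interval_distance,
    delta = format_num(pairs$delta),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pair table written by [write_pair_table()]
#' @param path file path.
#' @return data.frame in the eight-column pair format.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
              colClasses = list(character = c("gene1", "gene2")))
  need <- c("gene1", "gene2", "r_control", "r_case",
            "bin_control", "bin_case", "interval_distance", "delta")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("pair table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("r_control", "r_case", "delta")) dt[[col]] <- as.numeric(dt[[col]])
  for (col in c("bin_control", "bin_case", "interval_distance")) {
    dt[[col]] <- as.integer(dt[[col]])
  }
  dt[need]
}

#' Write a transition matrix as labeled TSV
#'
#' Writes the 8x8 control-to-case pair counts (and, optionally, the row
#' percentages to five decimal places) with rows labeled
#' `control_[a,b)` and columns `case_[a,b)`.
#'
#' @param tm a [build_transition_matrix()] result.
#' @param path_counts counts output path.
#' @param path_percentages optional percentages output path.
#' @export
write_transition_matrix <- function(tm, path_counts, path_percentages = NULL) {
  cnt <- tm$counts
  df <- data.frame(interval = rownames(cnt), cnt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path_counts, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_percentages)) {
    pct <- matrix(sprintf("%.5f", tm$row_percentages), nrow(cnt),
                  dimnames = dimnames(tm$row_percentages))
    pct[is.nan(tm$row_percentages)] <- "NA"
    dfp <- data.frame(interval = rownames(cnt), pct, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(dfp, path_percentages, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path_counts)
}

#' Read a labeled transition-count TSV
#'
#' Reads counts written by [write_transition_matrix()] (or any labeled 8x8
#' count table in that layout) back into a transition matrix object.
#'
#' @param path file path.
#' @param n_excluded pairs undefined in either condition (not represented in
#'   the counts).
#' @param scheme interval scheme the counts refer to.
#' @return a transition matrix (see [transition_matrix_from_counts()]).
#' @export
read_transition_counts <- function(path, n_excluded = 0L, scheme = interval_scheme()) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  cnt <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(cnt) <- dt[[1L]]
  transition_matrix_from_counts(cnt, n_excluded = n_excluded, scheme = scheme)
}

#' Write a gene list, one symbol per line
#'
#' The plain-text export format consumed by external enrichment tools
#' (e.g. DAVID).
#'
#' @param genes character vector of gene symbols.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
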