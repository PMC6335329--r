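#' Construct and validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with features (probes or genes) in
#' rows and samples in columns, values in `[0, 1]` (methylation beta values),
#' and a `level` attribute recording whether rows are probes or genes.
#' Missing values (`NA`) are permitted; see [aggregate_probes_to_genes()] for
#' how they are handled downstream.
#'
#' @param values numeric matrix, features x samples, with unique non-empty
#'   row and column names.
#' @param level `"gene"` or `"probe"`.
#' @param tol values outside `[0, 1]` by at most `tol` are clamped to the
#'   boundary; larger excursions are an error naming the offending cell.
#' @return the validated matrix with a `level` attribute.
#' @export
beta_matrix <- function(values, level = c("gene", "probe"), tol = 1e-9) {
  level <- match.arg(level)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("beta matrix must have row (feature) and column (sample) names")
  }
  if (anyDuplicated(fid)) {
    stop("duplicated feature ids: ", paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  bad <- which(!is.na(values) & (values < -tol | values > 1 + tol))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf(
      "beta value %g out of [0,1] at feature '%s', sample '%s' (%d offending cell(s))",
      values[bad[1]], fid[i], sid[j], length(bad)
    ))
  }
  if (any(!is.na(values) & values > 1)) values[!is.na(values) & values > 1] <- 1
  if (any(!is.na(values) & values < 0)) values[!is.na(values) & values < 0] <- 0
  inf <- which(is.infinite(values))
  if (length(inf)) stop("non-finite beta values present")
  attr(values, "level") <- level
  values
}

#' Feature level of a beta matrix
#' @param x a matrix created by [beta_matrix()] or a reader.
#' @return `"gene"`, `"probe"`, or `NA` if unset.
#' @export
beta_level <- function(x) {
  lv <- attr(x, "level", exact = TRUE)
  if (is.null(lv)) NA_character_ else lv
}

#' Construct and validate a phenotype table
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group case/control assignment; tokens are matched
#'   case-insensitively against `"case"` and `"control"`.
#' @return data.frame with columns `sample_id` (character) and `group`
#'   (factor with levels `control`, `case`).
#' @export
phenotype_table <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample ids in phenotype table: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  tok <- tolower(trimws(as.character(group)))
  bad <- setdiff(unique(tok), c("case", "control"))
  if (length(bad)) {
    stop("unknown group token(s): ", paste(bad, collapse = ", "),
         "; accepted tokens are 'case' and 'control' (case-insensitive)")
  }
  data.frame(
    sample_id = sample_id,
    group = factor(tok, levels = c("control", "case")),
    stringsAsFactors = FALSE
  )
}

# Match a phenotype table against a beta matrix's samples and return the
# sample ids of one group. Every matrix sample must be phenotyped exactly once.
group_samples <- function(beta, phenotypes, group = c("case", "control")) {
  group <- match.arg(group)
  sid <- colnames(beta)
  missing <- setdiff(sid, phenotypes$sample_id)
  if (length(missing)) {
    stop("samples absent from phenotype table: ", paste(missing, collapse = ", "))
  }
  grp <- phenotypes$group[match(sid, phenotypes$sample_id)]
  sid[grp == group]
}
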