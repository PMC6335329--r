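#' Published reference transition counts and shared pairs
#'
#' The package ships, as plain-text fixtures, the published 8x8
#' control-to-case transition counts for the rheumatoid arthritis
#' (GSE42861) and Parkinson's disease (GSE111629) blood-methylation
#' cohorts, and the nine gene pairs reported as shared large-change pairs
#' between the two diseases (case/control correlations printed to three
#' decimals). They let the interval-transition and cross-disease operations
#' be exercised against reported results without access to the full GEO
#' data.
#'
#' @param disease `"RA"` or `"PD"`.
#' @return `reference_transition_counts()`: a transition matrix object
#'   (see [transition_matrix_from_counts()]). `reference_shared_pairs()`: a
#'   data.frame with columns `gene1`, `gene2`, `r_case_ra`, `r_control_ra`,
#'   `r_case_pd`, `r_control_pd`.
#' @export
reference_transition_counts <- function(disease = c("RA", "PD")) {
  disease <- match.arg(disease)
  path <- system.file("extdata",
                      sprintf("%s_transition_counts_reference.tsv",
                              tolower(disease)),
                      package = "comethdiff", mustWork = TRUE)
  read_transition_counts(path)
}

#' @rdname reference_transition_counts
#' @export
reference_shared_pairs <- function() {
  path <- system.file("extdata", "shared_pairs_reference.tsv",
                      package = "comethdiff", mustWork = TRUE)
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
              colClasses = list(character = c("gene1", "gene2")))
  dt
}
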