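#' Intersect large-change pair sets from two diseases
#'
#' A pair's identity is its lexicographically sorted symbol tuple, so the
#' intersection is order-invariant. Correlations from both diseases are
#' carried through; the result is sorted by `(gene1, gene2)`.
#'
#' @param a,b large-change pair tables (columns `gene1`, `gene2`,
#'   `r_control`, `r_case`; extra columns ignored) for diseases A and B.
#' @param require_same_direction if `TRUE`, additionally require
#'   `sign(r_case - r_control)` to agree between the two diseases.
#' @return data.frame with columns `gene1`, `gene2`, `r_control_a`,
#'   `r_case_a`, `r_control_b`, `r_case_b`.
#' @export
intersect_pairs <- function(a, b, require_same_direction = FALSE) {
  canon <- function(p) {
    g1 <- pmin(p$gene1, p$gene2)
    g2 <- pmax(p$gene1, p$gene2)
    data.frame(gene1 = g1, gene2 = g2,
               r_control = p$r_control, r_case = p$r_case,
               key = paste(g1, g2, sep = "\x1f"),
               stringsAsFactors = FALSE)
  }
  ca <- canon(a)
  cb <- canon(b)
  if (anyDuplicated(ca$key) || anyDuplicated(cb$key)) {
    stop("pair sets must not contain duplicate pairs")
  }
  m <- match(ca$key, cb$key)
  hit <- !is.na(m)
  out <- data.frame(
    gene1 = ca$gene1[hit],
    gene2 = ca$gene2[hit],
    r_control_a = ca$r_control[hit],
    r_case_a = ca$r_case[hit],
    r_control_b = cb$r_control[m[hit]],
    r_case_b = cb$r_case[m[hit]],
    stringsAsFactors = FALSE
  )
  if (require_same_direction) {
    same <- sign(out$r_case_a - out$r_control_a) ==
      sign(out$r_case_b - out$r_control_b)
    out <- out[same, , drop = FALSE]
  }
  out <- out[order_c(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unique genes in a pair set
#'
#' The sorted, de-duplicated union of both gene columns — the list exported
#' for external GO/KEGG enrichment tools.
#'
#' @param pairs any pair table with `gene1` and `gene2` columns.
#' @return character vector of gene symbols in lexicographic order.
#' @export
unique_genes <- function(pairs) {
  sort_c(unique(c(pairs$gene1, pairs$gene2)))
}
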