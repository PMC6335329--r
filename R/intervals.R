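#' The eight-interval correlation scheme
#'
#' The fixed classification of a Pearson correlation into eight named
#' intervals, from strongest negative `[-1, -0.75)` to strongest positive
#' `[0.75, 1]`. Bins 1-7 are half-open `[a, b)`; the last bin is closed.
#' Custom edges are supported, but the default is the standard scheme.
#'
#' @param edges strictly increasing break points spanning the correlation
#'   range; the default gives eight bins of width 0.25 over `[-1, 1]`.
#' @param labels one name per bin.
#' @return an `interval_scheme` object.
#' @export
interval_scheme <- function(edges = c(-1, -0.75, -0.5, -0.25, 0, 0.25, 0.5, 0.75, 1),
                            labels = NULL) {
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing with at least 2 values")
  }
  n_bins <- length(edges) - 1L
  if (is.null(labels)) {
    if (n_bins == 8L && isTRUE(all.equal(edges, seq(-1, 1, by = 0.25)))) {
      labels <- c("strongest negative correlation", "strong negative correlation",
                  "weak negative correlation", "weakest negative correlation",
                  "weakest positive correlation", "weak positive correlation",
                  "strong positive correlation", "strongest positive correlation")
    } else {
      labels <- sprintf("bin%d", seq_len(n_bins))
    }
  }
  if (length(labels) != n_bins) stop("need one label per bin")
  structure(list(edges = edges, labels = labels, n_bins = n_bins),
            class = "interval_scheme")
}

# "control_[-1,-0.75)" ... "control_[0.75,1]" style axis labels.
interval_names <- function(scheme, prefix) {
  e <- scheme$edges
  n <- scheme$n_bins
  close <- c(rep(")", n - 1L), "]")
  sprintf("%s_[%g,%g%s", prefix, e[-length(e)], e[-1L], close)
}

#' Assign correlations to interval bins
#'
#' @param r correlations in `[-1, 1]` (vectorized). Undefined (`NA`) values
#'   are an error: exclude them before binning.
#' @param scheme an [interval_scheme()].
#' @param tol values beyond the outer edges by at most `tol` are clamped.
#' @return integer bin indices in `1..n_bins`.
#' @export
assign_interval <- function(r, scheme = interval_scheme(), tol = 1e-12) {
  if (anyNA(r)) stop("undefined correlation passed to assign_interval; exclude NA first")
  e <- scheme$edges
  lo <- e[1L]
  hi <- e[length(e)]
  if (any(r < lo - tol | r > hi + tol)) {
    stop("correlation outside [", lo, ", ", hi, "]: ",
         r[which(r < lo - tol | r > hi + tol)[1L]])
  }
  r <- pmin(pmax(r, lo), hi)
  findInterval(r, e, rightmost.closed = TRUE)
}

#' Interval-crossing distance between two bins
#'
#' A pair "crossed k intervals" when the absolute difference between its
#' control bin and case bin is k.
#'
#' @param bin_control,bin_case integer bin indices.
#' @param n_bins number of bins in the scheme (for validation).
#' @return `abs(bin_case - bin_control)`.
#' @export
interval_distance <- function(bin_control, bin_case, n_bins = 8L) {
  ok <- function(b) all(is.na(b) | (b >= 1L & b <= n_bins & b == floor(b)))
  if (!ok(bin_control) || !ok(bin_case)) stop("bin indices must lie in 1..", n_bins)
  abs(as.integer(bin_case) - as.integer(bin_control))
}

#' Annotate a pair table with bins, interval distance and delta
#'
#' Adds `bin_control`, `bin_case`, `interval_distance` and
#' `delta = r_case - r_control` to a pair-correlation table. Rows undefined
#' in either condition get `NA` annotation. Already-annotated tables are
#' returned unchanged.
#'
#' @param pairs data.frame with `gene1`, `gene2`, `r_control`, `r_case`.
#' @param scheme an [interval_scheme()].
#' @return the annotated data.frame.
#' @export
annotate_pairs <- function(pairs, scheme = interval_scheme()) {
  need <- c("gene1", "gene2", "r_control", "r_case")
  if (!all(need %in% names(pairs))) {
    stop("pair table needs columns: ", paste(need, collapse = ", "))
  }
  full <- c("bin_control", "bin_case", "interval_distance", "delta")
  if (all(full %in% names(pairs))) return(pairs)
  def <- !is.na(pairs$r_control) & !is.na(pairs$r_case)
  bc <- rep(NA_integer_, nrow(pairs))
  ba <- rep(NA_integer_, nrow(pairs))
  bc[def] <- assign_interval(pairs$r_control[def], scheme)
  ba[def] <- assign_interval(pairs$r_case[def], scheme)
  pairs$bin_control <- bc
  pairs$bin_case <- ba
  pairs$interval_distance <- abs(ba - bc)
  pairs$delta <- pairs$r_case - pairs$r_control
  pairs
}

#' Build the control-to-case transition matrix
#'
#' Counts gene pairs by (control bin, case bin) on the interval scheme:
#' rows are the control bin, columns the case bin. Pairs undefined in either
#' condition are excluded from the counts and reported in `n_excluded`, so
#' `sum(counts) + n_excluded` equals the number of input pairs. Row
#' percentages are `100 * count / row sum` in full precision (rows with a
#' zero sum are `NaN`).
#'
#' @param pairs a pair-correlation table.
#' @param scheme an [interval_scheme()].
#' @return a `transition_matrix` object: list with `counts`,
#'   `row_percentages`, `n_excluded`, `n_pairs`, `scheme`.
#' @export
build_transition_matrix <- function(pairs, scheme = interval_scheme()) {
  pairs <- annotate_pairs(pairs, scheme)
  def <- !is.na(pairs$bin_control) & !is.na(pairs$bin_case)
  nb <- scheme$n_bins
  counts <- table(factor(pairs$bin_control[def], levels = seq_len(nb)),
                  factor(pairs$bin_case[def], levels = seq_len(nb)))
  counts <- matrix(as.numeric(counts), nb, nb,
                   dimnames = list(interval_names(scheme, "control"),
                                   interval_names(scheme, "case")))
  transition_matrix_from_counts(counts, n_excluded = sum(!def),
                                scheme = scheme, n_pairs = nrow(pairs))
}

#' Wrap an existing 8x8 count grid as a transition matrix
#'
#' For count tables obtained elsewhere (e.g. published tables used as
#' reference fixtures). Rows are control bins, columns case bins.
#'
#' @param counts numeric matrix of non-negative integers, one row/column per
#'   bin of `scheme`.
#' @param n_excluded pairs undefined in either condition.
#' @param scheme an [interval_scheme()].
#' @param n_pairs total input pairs; defaults to `sum(counts) + n_excluded`.
#' @return a `transition_matrix` object.
#' @export
transition_matrix_from_counts <- function(counts, n_excluded = 0L,
                                          scheme = interval_scheme(),
                                          n_pairs = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  nb <- scheme$n_bins
  if (!all(dim(counts) == nb)) {
    stop("counts must be ", nb, "x", nb, " for this scheme")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(rownames(counts))) rownames(counts) <- interval_names(scheme, "control")
  if (is.null(colnames(counts))) colnames(counts) <- interval_names(scheme, "case")
  rs <- rowSums(counts)
  pct <- 100 * counts / rs
  if (is.null(n_pairs)) n_pairs <- sum(counts) + n_excluded
  structure(
    list(counts = counts, row_percentages = pct,
         n_excluded = as.numeric(n_excluded), n_pairs = as.numeric(n_pairs),
         scheme = scheme),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Transition matrix:", sum(x$counts), "pairs counted,",
      x$n_excluded, "excluded (undefined)\n")
  print(x$counts)
  invisible(x)
}

distance_grid <- function(tm) {
  nb <- tm$scheme$n_bins
  abs(outer(seq_len(nb), seq_len(nb), "-"))
}

#' Pairs crossing at least k intervals
#'
#' @param tm a transition matrix.
#' @param k minimum interval distance, `0..(n_bins - 1)`.
#' @return the total count over cells with `|i - j| >= k`.
#' @export
count_by_min_distance <- function(tm, k) {
  nb <- tm$scheme$n_bins
  if (k < 0 || k > nb - 1L) stop("k must lie in 0..", nb - 1L)
  sum(tm$counts[distance_grid(tm) >= k])
}

#' Pairs crossing exactly k intervals
#'
#' @param tm a transition matrix.
#' @param k exact interval distance, `0..(n_bins - 1)`.
#' @return the total count over cells with `|i - j| == k`.
#' @export
count_by_exact_distance <- function(tm, k) {
  nb <- tm$scheme$n_bins
  if (k < 0 || k > nb - 1L) stop("k must lie in 0..", nb - 1L)
  sum(tm$counts[distance_grid(tm) == k])
}

#' Extract large-change gene pairs
#'
#' Selects the pairs whose co-methylation moved at least `min_distance`
#' intervals between control and case, annotated with bins, distance and
#' `delta = r_case - r_control`. Pairs undefined in either condition are
#' never selected.
#'
#' @param pairs a pair-correlation table.
#' @param scheme an [interval_scheme()].
#' @param min_distance minimum interval distance, `1..(n_bins - 1)`.
#' @return the annotated subset, ordered by `(gene1, gene2)`.
#' @export
extract_large_change_pairs <- function(pairs, scheme = interval_scheme(),
                                       min_distance = 3L) {
  nb <- scheme$n_bins
  if (min_distance < 1 || min_distance > nb - 1L) {
    stop("min_distance must lie in 1..", nb - 1L)
  }
  pairs <- annotate_pairs(pairs, scheme)
  keep <- !is.na(pairs$interval_distance) & pairs$interval_distance >= min_distance
  out <- pairs[keep, , drop = FALSE]
  out <- out[order_c(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter pairs by absolute correlation change
#'
#' Keeps pairs with `|r_case - r_control|` strictly greater than
#' `threshold`. Pairs exactly at the threshold are excluded, counted and
#' reported via attribute `n_boundary` (boundary pairs are worth inspecting
#' since printed-precision deltas can tie the cutoff).
#'
#' @param pairs an annotated pair table (annotated on the fly if needed).
#' @param threshold non-negative cutoff on `|delta|` (default 0.8).
#' @param scheme interval scheme for on-the-fly annotation.
#' @return the filtered table with attribute `n_boundary`.
#' @export
filter_by_delta <- function(pairs, threshold = 0.8, scheme = interval_scheme()) {
  if (threshold < 0) stop("threshold must be >= 0")
  pairs <- annotate_pairs(pairs, scheme)
  ad <- abs(pairs$delta)
  keep <- !is.na(ad) & ad > threshold
  n_boundary <- sum(!is.na(ad) & ad == threshold)
  if (n_boundary > 0L) {
    message(n_boundary, " pair(s) with |delta| exactly at the threshold excluded")
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_boundary") <- n_boundary
  out
}
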