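#' Pearson co-methylation coefficient of two gene vectors
#'
#' The co-methylation of genes i and j across the n samples of one condition
#' is the sample Pearson correlation
#' \deqn{r(i,j) = \frac{1}{n-1} \sum_{k=1}^{n}
#'   \left(\frac{b_{i,k} - \bar b_i}{S_i}\right)
#'   \left(\frac{b_{j,k} - \bar b_j}{S_j}\right)}
#' with \eqn{S_i, S_j} the (n-1)-denominator standard deviations. The result
#' is undefined (`NA`) when either gene is constant across samples.
#'
#' @param x,y numeric vectors of equal length `n >= 2`, same sample order.
#' @param tol floating-point tolerance: results within `tol` beyond
#'   `[-1, 1]` are clamped to the boundary.
#' @return the correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pearson <- function(x, y, tol = 1e-12) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples, got ", n)
  mx <- mean(x)
  my <- mean(y)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- sum((x - mx) * (y - my)) / ((n - 1) * sx * sy)
  if (r > 1 && r <= 1 + tol) r <- 1
  if (r < -1 && r >= -1 - tol) r <- -1
  r
}

# Row-standardize a genes x samples matrix with (n-1)-denominator SDs.
# Zero-variance rows become all-NA so their correlations propagate as NA.
standardize_rows <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  cx <- x - m
  s <- sqrt(rowSums(cx^2) / (n - 1))
  z <- cx / s
  z[s == 0, ] <- NA_real_
  z
}

# Upper-triangle correlation vector for a genes x samples matrix, row-major
# over pairs (i < j) of the given row order, computed in row-block chunks.
pair_cor_vector <- function(x, chunk_size = 512L) {
  g <- nrow(x)
  n <- ncol(x)
  if (g < 2L) stop("need at least 2 genes")
  if (n < 2L) stop("need at least 2 samples")
  z <- standardize_rows(unclass(x))
  out <- numeric(g * (g - 1) / 2)
  pos <- 1L
  i0 <- 1L
  while (i0 < g) {
    i1 <- min(i0 + chunk_size - 1L, g - 1L)
    rb <- tcrossprod(z[i0:i1, , drop = FALSE], z) / (n - 1)
    for (i in i0:i1) {
      m <- g - i
      out[pos:(pos + m - 1L)] <- rb[i - i0 + 1L, (i + 1L):g]
      pos <- pos + m
    }
    i0 <- i1 + 1L
  }
  # crossprod can drift a few ulp past +/-1; clamp to the mathematical range
  pmin(pmax(out, -1), 1)
}

#' All-pairs co-methylation for case and control conditions
#'
#' Computes the Pearson co-methylation coefficient of every unordered gene
#' pair, separately within the case samples and within the control samples.
#' Genes are put in lexicographic (C-locale) order and pairs are enumerated
#' row-major over the upper triangle, giving `g (g - 1) / 2` rows for `g`
#' genes. The engine works in rectangular row-block chunks so the full
#' `g x g` correlation matrix is never materialized; results are identical
#' for any `chunk_size`.
#'
#' Pairs involving a zero-variance (constant) gene in a condition get `NA`
#' for that condition's correlation; the number of rows with an undefined
#' correlation in either condition is attached as attribute `n_undefined`.
#'
#' @param genes gene-level beta matrix (genes x samples).
#' @param phenotypes phenotype table covering every sample column.
#' @param chunk_size rows per block (tunes memory, not results).
#' @return data.frame with columns `gene1`, `gene2`, `r_control`, `r_case`
#'   (`gene1 < gene2` lexicographically) and attribute `n_undefined`.
#' @export
all_pairs_correlations <- function(genes, phenotypes, chunk_size = 512L) {
  if (nrow(genes) < 2L) stop("need at least 2 genes")
  ord <- order_c(rownames(genes))
  genes <- genes[ord, , drop = FALSE]
  ids <- rownames(genes)
  g <- length(ids)

  r_by_group <- lapply(c("control", "case"), function(grp) {
    sid <- group_samples(genes, phenotypes, grp)
    if (length(sid) < 2L) {
      stop("phenotype group '", grp, "' has ", length(sid),
           " sample(s); need at least 2")
    }
    pair_cor_vector(genes[, sid, drop = FALSE], chunk_size = chunk_size)
  })

  i <- rep.int(seq_len(g - 1L), times = (g - 1L):1L)
  j <- sequence((g - 1L):1L, from = 2L:g)
  out <- data.frame(
    gene1 = ids[i],
    gene2 = ids[j],
    r_control = r_by_group[[1L]],
    r_case = r_by_group[[2L]],
    stringsAsFactors = FALSE
  )
  attr(out, "n_undefined") <- sum(is.na(out$r_control) | is.na(out$r_case))
  out
}

#' Summarize one condition's correlation distribution
#'
#' Mean, SD (with the (n-1) denominator) and an equal-width histogram over
#' `[-1, 1]` of the defined correlations, as used to compare global
#' co-methylation between conditions.
#'
#' @param r numeric vector of correlations; `NA` (undefined) entries are
#'   excluded and counted.
#' @param n_bins number of equal-width histogram bins over `[-1, 1]`.
#' @return list with `n_pairs`, `mean_r`, `sd_r`, `breaks`, `counts`,
#'   `n_undefined`.
#' @export
summarize_distribution <- function(r, n_bins = 40L) {
  n_undef <- sum(is.na(r))
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("no defined correlations to summarize")
  if (any(r < -1 | r > 1)) stop("correlations outside [-1, 1]")
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  width <- 2 / n_bins
  bin <- pmin(floor((r + 1) / width) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  list(
    n_pairs = length(r),
    mean_r = mean(r),
    sd_r = if (length(r) > 1L) sd(r) else 0,
    breaks = breaks,
    counts = counts,
    n_undefined = n_undef
  )
}

#' Number of unordered gene pairs
#'
#' `n (n - 1) / 2`, computed exactly (21,225 genes give 225,239,700 pairs).
#'
#' @param n_genes non-negative gene count.
#' @return the pair count as a double (exact for any realistic `n`).
#' @export
count_pairs <- function(n_genes) {
  if (any(n_genes < 0) || any(n_genes != floor(n_genes))) {
    stop("n_genes must be a non-negative integer")
  }
  n <- as.numeric(n_genes)
  n * (n - 1) / 2
}
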