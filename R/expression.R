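## Library-size normalization and gene-presence filtering.
##
## Counts are normalized by the median-of-ratios procedure: a pseudo-
## reference sample is formed from per-gene geometric means (over genes
## positive in every sample), and each sample's size factor is the median
## of its count/reference ratios over those genes.  Long-RNA and tRNA
## count matrices are meant to be normalized separately, never jointly.

#' Median-of-ratios size factors
#'
#' The geometric means are computed in log space; genes with any zero
#' count are excluded from the reference set.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stopf(paste("no gene has strictly positive counts in every sample;",
                "filter the matrix before computing size factors"))
  logc <- log(counts[pos, , drop = FALSE])
  logref <- rowMeans(logc)
  sf <- exp(apply(logc - logref, 2, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts Genes x samples matrix.
#' @param factors Positive size factors, one per sample (as from
#'   [size_factors()]).
#' @return Real-valued matrix `counts[g, s] / factors[s]`.
#' @export
normalize_counts <- function(counts, factors) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts))
    stopf("need one size factor per sample")
  if (any(factors <= 0)) stopf("size factors must be positive")
  sweep(counts, 2, factors, "/")
}

#' Gene-presence filter
#'
#' Retains genes with a nonzero count in strictly more than
#' `min_presence_fraction` of the samples (so exactly the threshold
#' fraction is dropped).  Used to restrict the tRNA dataset to genes
#' covered in more than 90% of samples.
#'
#' @param counts Genes x samples matrix.
#' @param min_presence_fraction Fraction in `(0, 1]`, default 0.9.
#' @return Character vector of retained gene ids.
#' @export
presence_filter <- function(counts, min_presence_fraction = 0.9) {
  if (min_presence_fraction <= 0 || min_presence_fraction > 1)
    stopf("min_presence_fraction must lie in (0, 1]")
  counts <- as.matrix(counts)
  frac <- rowMeans(counts > 0)
  rownames(counts)[frac > min_presence_fraction]
}
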