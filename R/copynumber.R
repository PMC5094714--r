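## mtDNA copy-number estimation from DNA coverage.
##
## The mtDNA copy number of a sample is estimated as the ratio between its
## mean per-base DNA read coverage over mtDNA positions 1-16,499 and its
## mean per-base coverage over 22 fixed autosomal windows (100,000 bases
## starting at position 20,100,000 on each autosome).  Since each cell
## carries two autosomal genome copies' worth of coverage baseline, the
## raw ratio is reported as the copy-number estimate, exactly as the
## coverage-ratio definition prescribes.

#' mtDNA interval and autosomal window used for copy-number estimation
#' @return Integer vector `c(start, end)`, inclusive.
#' @export
mt_coverage_interval <- function() c(1L, 16499L)

#' @rdname mt_coverage_interval
#' @export
autosomal_window <- function() c(20100000L, 20199999L)

#' Mean per-base coverage over an interval
#'
#' @param track Either a numeric vector of per-base depths (position =
#'   index) or a data frame with columns `position` and `depth` (positions
#'   absent from the data frame count as zero coverage).
#' @param interval Inclusive `c(start, end)` pair, 1-based.
#' @return Arithmetic mean depth over the interval.
#' @export
interval_mean_coverage <- function(track, interval) {
  start <- interval[1]; end <- interval[2]
  if (end < start) stopf("empty interval [%s, %s]", start, end)
  len <- end - start + 1
  if (is.data.frame(track)) {
    if (!all(c("position", "depth") %in% names(track)))
      stopf("track data frame needs columns position, depth")
    sel <- track$position >= start & track$position <= end
    return(sum(track$depth[sel]) / len)
  }
  if (start < 1 || end > length(track))
    stopf("interval [%s, %s] outside track bounds", start, end)
  mean(track[start:end])
}

#' Copy-number estimate from coverage summaries
#'
#' @param mt_mean Mean per-base mtDNA coverage.
#' @param autosomal_means Numeric vector of 22 autosomal window mean
#'   coverages (all windows are equal length, so their unweighted mean
#'   equals the pooled per-base mean).
#' @param require_22 If `TRUE` (default), exactly 22 windows are required.
#' @return List with `mt_mean`, `autosomal_mean` and `copy_number`.
#' @export
estimate_copy_number <- function(mt_mean, autosomal_means,
                                 require_22 = TRUE) {
  if (require_22 && length(autosomal_means) != 22L)
    stopf("expected 22 autosomal window means, got %d",
          length(autosomal_means))
  auto <- mean(autosomal_means)
  if (is.na(auto) || auto <= 0)
    stopf("autosomal mean coverage must be positive")
  list(mt_mean = mt_mean, autosomal_mean = auto,
       copy_number = mt_mean / auto)
}

#' Per-sample copy numbers from a coverage summary table
#'
#' @param coverage Data frame as produced by [simulate_dna_coverage()]:
#'   `sample_id`, `mt_mean` and 22 `auto_chr*` columns.
#' @return Data frame with `sample_id` and `copy_number`.
#' @export
estimate_copy_numbers <- function(coverage) {
  auto_cols <- grep("^auto_", names(coverage), value = TRUE)
  cn <- vapply(seq_len(nrow(coverage)), function(i) {
    estimate_copy_number(coverage$mt_mean[i],
                         as.numeric(coverage[i, auto_cols]))$copy_number
  }, numeric(1))
  data.frame(sample_id = coverage$sample_id, copy_number = cn,
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis comparison of copy numbers between groups
#'
#' Rank-based H statistic with tie correction and a chi-squared p-value on
#' `groups - 1` degrees of freedom (via [stats::kruskal.test()]).  An
#' optional permutation p-value re-randomizes group labels, useful for
#' very small groups where the chi-squared approximation is doubtful.
#'
#' @param values Numeric vector.
#' @param groups Group labels, at least two distinct values.
#' @param permute If `TRUE`, also compute a Monte-Carlo permutation
#'   p-value of the H statistic.
#' @param n_perm Number of permutations.
#' @return List with `H`, `df`, `p.value`, `n` and (optionally)
#'   `p.permutation`.
#' @export
kruskal_wallis <- function(values, groups, permute = FALSE,
                           n_perm = 10000L) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stopf("need at least two groups")
  kt <- stats::kruskal.test(values, groups)
  out <- list(H = unname(kt$statistic), df = unname(kt$parameter),
              p.value = kt$p.value, n = length(values))
  if (permute) {
    h0 <- replicate(n_perm, {
      stats::kruskal.test(values, sample(groups))$statistic
    })
    out$p.permutation <- (1 + sum(h0 >= out$H)) / (1 + n_perm)
  }
  out
}
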