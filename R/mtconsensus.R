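## Consensus reconstruction from pileups.
##
## The polycistronic transcription of the mitochondrial genome gives
## RNA-seq coverage over essentially the whole mtDNA, so a per-sample
## consensus sequence can be reconstructed directly from base-count
## pileups by a majority rule.  Coordinates are 1-based on the linear
## 16,569-base mtDNA frame; circularity is ignored because mapping has
## already resolved the origin.  Indels and heteroplasmy are out of scope:
## the site matrix is substitution-only.

#' Majority-rule consensus from a base-count pileup
#'
#' At each position the highest-count base is emitted iff the position's
#' depth is at least `min_depth` and the base's fraction of the depth is at
#' least `min_major_fraction`; otherwise (including ties for the top count)
#' the position is called `N`.
#'
#' @param pileup Integer matrix `positions x 4` with columns
#'   `A`, `C`, `G`, `T` of base counts.
#' @param min_depth Minimum depth to call a base (>= 1).
#' @param min_major_fraction Required majority fraction, in `(0.5, 1]`.
#' @param sample_id Optional sample id attached to the result.
#' @param ref_length If given, the pileup must have exactly this many rows.
#' @return A single string over `{A,C,G,T,N}` with attributes `sample_id`
#'   and `major_fraction` (per-position fraction of the top base, `NA` at
#'   zero depth).
#' @export
call_consensus <- function(pileup, min_depth = 5L, min_major_fraction = 0.7,
                           sample_id = NULL, ref_length = NULL) {
  pileup <- as.matrix(pileup)
  if (ncol(pileup) != 4L)
    stopf("pileup must have 4 base-count columns (A, C, G, T)")
  if (!is.null(colnames(pileup)) && !identical(colnames(pileup), BASES))
    pileup <- pileup[, BASES, drop = FALSE]
  if (!is.null(ref_length) && nrow(pileup) != ref_length)
    stopf("pileup has %d positions but the reference has %d",
          nrow(pileup), ref_length)
  if (min_depth < 1) stopf("min_depth must be >= 1")
  if (min_major_fraction <= 0.5 || min_major_fraction > 1)
    stopf("min_major_fraction must lie in (0.5, 1]")
  if (any(pileup < 0)) stopf("negative base counts in pileup")

  depth <- rowSums(pileup)
  mx <- pmax(pileup[, 1L], pileup[, 2L], pileup[, 3L], pileup[, 4L])
  n_at_max <- (pileup[, 1L] == mx) + (pileup[, 2L] == mx) +
    (pileup[, 3L] == mx) + (pileup[, 4L] == mx)
  call <- BASES[max.col(pileup, ties.method = "first")]
  no_call <- n_at_max > 1L | depth < min_depth |
    mx < min_major_fraction * depth
  call[no_call] <- "N"
  out <- paste(call, collapse = "")
  attr(out, "sample_id") <- sample_id
  attr(out, "major_fraction") <- ifelse(depth > 0, mx / depth, NA_real_)
  out
}

#' Call substitutions of a consensus against the reference
#'
#' Emits one call per position where the consensus base (one of A/C/G/T)
#' differs from the reference.  Positions called `N` and positions on the
#' RDD mask are excluded, so universal RNA-DNA differences never enter the
#' variant list.
#'
#' @param consensus Consensus string from [call_consensus()].
#' @param reference Reference string of the same length.
#' @param rdd_sites Integer vector of masked RDD positions.
#' @return Data frame with columns `position`, `ref`, `alt`, `af`
#'   (major-allele fraction at the position when the consensus carries it,
#'   otherwise `NA`).
#' @export
call_variants <- function(consensus, reference, rdd_sites = integer()) {
  cs <- split_bases(consensus)
  rf <- split_bases(reference)
  if (length(cs) != length(rf))
    stopf("consensus length %d != reference length %d",
          length(cs), length(rf))
  idx <- which(cs != rf & cs != "N")
  idx <- setdiff(idx, as.integer(rdd_sites))
  af <- attr(consensus, "major_fraction")
  data.frame(
    position = idx,
    ref = rf[idx],
    alt = cs[idx],
    af = if (is.null(af)) rep(NA_real_, length(idx)) else af[idx],
    stringsAsFactors = FALSE
  )
}

#' Cohort polymorphic-site matrix
#'
#' Aligns the consensus sequences (positionally co-linear by construction),
#' collects every position at which any sample carries a non-reference,
#' non-RDD substitution, and returns the per-sample allele at those
#' positions (`N` allowed).  Sites where every non-major allele has fewer
#' than `min_carriers` carriers are dropped; at most the three most
#' frequent alleles per site are retained, rarer alleles being set to `N`.
#'
#' @param consensuses Named list (or vector) of consensus strings.
#' @param reference Reference string.
#' @param rdd_sites Integer vector of masked RDD positions.
#' @param min_carriers Minimum number of carriers of a non-major allele
#'   for the site to be kept (default 10).
#' @return Character matrix sites x samples with rownames the positions and
#'   attribute `ploidy = "haploid"`; zero rows when nothing is polymorphic.
#' @export
build_site_matrix <- function(consensuses, reference, rdd_sites = integer(),
                              min_carriers = 10L) {
  if (min_carriers < 1) stopf("min_carriers must be >= 1")
  if (length(consensuses) < 2L) stopf("need at least 2 samples")
  ids <- names(consensuses) %||% paste0("sample", seq_along(consensuses))
  chars <- do.call(rbind, lapply(consensuses, split_bases))
  rownames(chars) <- ids
  rf <- split_bases(reference)
  if (ncol(chars) != length(rf))
    stopf("consensus length does not match the reference")

  variant_any <- colSums(chars != rep(rf, each = nrow(chars)) &
                           chars != "N") > 0
  pos <- setdiff(which(variant_any), as.integer(rdd_sites))
  empty <- matrix(character(), nrow = 0, ncol = length(ids),
                  dimnames = list(NULL, ids))
  if (!length(pos)) {
    attr(empty, "ploidy") <- "haploid"
    return(empty)
  }

  m <- t(chars[, pos, drop = FALSE])
  rownames(m) <- as.character(pos)
  keep <- logical(length(pos))
  for (i in seq_along(pos)) {
    a <- m[i, ]
    tab <- sort(table(a[a != "N"]), decreasing = TRUE)
    if (length(tab) > 3L) {
      # cap at the three most frequent alleles
      drop_alleles <- names(tab)[-(1:3)]
      m[i, a %in% drop_alleles] <- "N"
      tab <- tab[1:3]
    }
    keep[i] <- length(tab) >= 2L && any(tab[-1L] >= min_carriers)
  }
  out <- m[keep, , drop = FALSE]
  attr(out, "ploidy") <- "haploid"
  out
}
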