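## Stratified split-half replication.
##
## The cohort is randomly re-divided into two groups many times while
## retaining the proportions of sex and population in each group.  For
## every division, each half is treated as an independent biological
## replicate: library-size normalization, site filters, the association
## scan and its Bonferroni family are all recomputed within the half.  A
## (site, allele, gene) association replicates in a division iff it is
## Bonferroni-significant in both halves (an "either half" mode is also
## available); genes whose associations replicate in more than a cutoff
## fraction (default 60%) of divisions are certified consistent.

#' Stratified random group assignment
#'
#' Within each stratum (the interaction of the given keys, e.g. sex x
#' population), samples are shuffled and dealt round-robin into
#' `n_groups`, so per-stratum group sizes differ by at most one.
#'
#' @param samples Sample table containing the strata key columns.
#' @param strata Character vector of column names defining the strata
#'   (default sex and population).
#' @param n_groups Number of groups (>= 2).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Integer group assignment (1..n_groups) named by `sample_id`.
#' @export
stratified_split <- function(samples, strata = c("sex", "population"),
                             n_groups = 2L, seed = NULL) {
  if (n_groups < 2L) stopf("n_groups must be >= 2")
  missing_keys <- setdiff(strata, names(samples))
  if (length(missing_keys))
    stopf("strata column(s) not in sample table: %s",
          paste(missing_keys, collapse = ", "))
  cell <- interaction(samples[, strata, drop = FALSE], drop = TRUE)
  assign_one <- function() {
    g <- integer(nrow(samples))
    for (lv in levels(cell)) {
      idx <- which(cell == lv)
      if (length(idx) < n_groups)
        warning(sprintf("stratum '%s' has fewer samples (%d) than groups",
                        lv, length(idx)), call. = FALSE)
      g[sample(idx)] <- rep_len(seq_len(n_groups), length(idx))
    }
    stats::setNames(g, samples$sample_id)
  }
  if (is.null(seed)) assign_one() else with_seed(seed, assign_one())
}

#' Run replicated split-half association analyses
#'
#' For each of `n_replicates` stratified re-divisions: split the cohort in
#' two, and within each half recompute median-of-ratios size factors,
#' re-apply the site filters, run the association scan, and apply the
#' half's own Bonferroni threshold.  A (site, allele, gene) pair
#' replicates in a division iff its p-value falls below the half's
#' threshold in both halves (`mode = "both"`, the default) or in at least
#' one (`mode = "either"`).
#'
#' @param counts Raw count matrix genes x samples.
#' @param genotypes Haploid site matrix sites x samples.
#' @param covariates Covariate data frame (one row per sample).
#' @param samples Sample table (for the stratification keys).
#' @param n_replicates Number of re-divisions (default 500).
#' @param alpha Family-wise error rate per half (default 0.05); the
#'   degenerate value `alpha >= 1` disables the correction, making every
#'   fitted test significant.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param strata Stratification keys (default sex and population).
#' @param mode `"both"` or `"either"` half significance criterion.
#' @param min_half_n Minimum usable half size; smaller halves skip the
#'   replicate (logged, denominator adjusted).
#' @param min_carriers,max_major_freq Site filters applied within each
#'   half.
#' @return A `replication_report` data frame: `site`, `allele`, `gene`,
#'   `n_replicates` (effective), `n_replicated`, `fraction`; attributes
#'   `mode`, `alpha`, `n_skipped`.
#' @export
run_replicates <- function(counts, genotypes, covariates, samples,
                           n_replicates = 500L, alpha = 0.05, seed = 1L,
                           strata = c("sex", "population"),
                           mode = c("both", "either"), min_half_n = 30L,
                           min_carriers = 10L, max_major_freq = 0.95) {
  mode <- match.arg(mode)
  if (n_replicates < 1L) stopf("n_replicates must be >= 1")
  counts <- as.matrix(counts)
  rep_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1L,
                                    n_replicates))
  tally <- new.env(parent = emptyenv())
  n_used <- 0L
  n_skipped <- 0L

  half_sig <- function(idx) {
    sf <- size_factors(counts[, idx, drop = FALSE])
    norm <- normalize_counts(counts[, idx, drop = FALSE], sf)
    g <- genotypes[, idx, drop = FALSE]
    attr(g, "ploidy") <- genotype_ploidy(genotypes)
    scan <- eqtl_scan(norm, g, covariates[idx, , drop = FALSE],
                      family = "replication", min_carriers = min_carriers,
                      max_major_freq = max_major_freq,
                      alpha = min(alpha, 0.999999))
    if (!nrow(scan)) return(character())
    thr <- if (alpha >= 1) Inf else attr(scan, "bonferroni")
    with(scan[scan$p < thr, , drop = FALSE],
         paste(site, allele, gene, sep = "\r"))
  }

  for (r in seq_len(n_replicates)) {
    grp <- stratified_split(samples, strata, 2L, seed = rep_seeds[r])
    idx1 <- which(grp == 1L)
    idx2 <- which(grp == 2L)
    if (length(idx1) < min_half_n || length(idx2) < min_half_n) {
      n_skipped <- n_skipped + 1L
      next
    }
    s1 <- half_sig(idx1)
    s2 <- half_sig(idx2)
    hits <- if (mode == "both") intersect(s1, s2) else union(s1, s2)
    for (k in hits) assign(k, (tally[[k]] %||% 0L) + 1L, envir = tally)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stopf("every replicate was skipped")

  keys <- ls(tally)
  parts <- if (length(keys)) do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    else matrix(character(), 0, 3)
  counts_rep <- if (length(keys))
    vapply(keys, function(k) tally[[k]], integer(1)) else integer()
  report <- data.frame(
    site = parts[, 1], allele = parts[, 2], gene = parts[, 3],
    n_replicates = rep(n_used, length(keys)),
    n_replicated = unname(counts_rep),
    stringsAsFactors = FALSE
  )
  report$fraction <- report$n_replicated / report$n_replicates
  report <- report[order(-report$fraction, report$site, report$gene), ,
                   drop = FALSE]
  rownames(report) <- NULL
  attr(report, "mode") <- mode
  attr(report, "alpha") <- alpha
  attr(report, "n_skipped") <- n_skipped
  class(report) <- c("replication_report", class(report))
  report
}

#' Genes passing the replication-consistency cutoff
#'
#' Returns the genes whose replication fraction strictly exceeds the
#' cutoff, grouped by the set of associated sites.
#'
#' @param report A [run_replicates()] report.
#' @param cutoff Fraction in `(0, 1]` (default 0.6).
#' @return Data frame with `gene`, `sites` (comma-separated associated
#'   sites), `max_fraction`; zero rows when nothing passes.
#' @export
consistency_report <- function(report, cutoff = 0.6) {
  if (cutoff <= 0 || cutoff > 1) stopf("cutoff must lie in (0, 1]")
  hit <- report[report$fraction > cutoff, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(gene = character(), sites = character(),
                      max_fraction = numeric(), stringsAsFactors = FALSE))
  agg <- lapply(split(hit, hit$gene), function(d) {
    data.frame(gene = d$gene[1],
               sites = paste(sort(unique(d$site)), collapse = ","),
               max_fraction = max(d$fraction), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$max_fraction, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
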