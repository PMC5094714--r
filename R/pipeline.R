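## End-to-end convenience wrappers tying the simulator to the analysis
## stages, used by the worked examples and the acceptance checks.

#' Cohort site matrix from true haplotypes
#'
#' Builds the haploid polymorphic-site matrix directly from each sample's
#' true clade sequence.  This equals the pileup -> consensus ->
#' variant-call path at sequencing error zero (the round-trip identity the
#' test suite asserts) and avoids materializing full-genome pileups for
#' large cohorts.
#'
#' @param samples Sample table from [simulate_cohort()].
#' @param haplotypes Output of [simulate_haplotypes()].
#' @param config The [sim_config()] (for the RDD mask).
#' @param min_carriers Carrier filter passed to [build_site_matrix()].
#' @return Haploid character matrix sites x samples.
#' @export
haplotype_site_matrix <- function(samples, haplotypes, config,
                                  min_carriers = 10L) {
  cons <- stats::setNames(unname(haplotypes$sequences[samples$clade]),
                          samples$sample_id)
  build_site_matrix(cons, haplotypes$reference,
                    config$rdd_sites$position, min_carriers)
}

#' Simulate a full study and assemble analysis-ready inputs
#'
#' Runs the generator end to end: haplotypes, cohort, counts, DNA
#' coverage, copy-number estimates, and the mtDNA site matrix (from true
#' haplotypes, or through the pileup -> consensus path when
#' `with_pileups = TRUE`).  The covariate table contains sex, lab and the
#' coverage-estimated mtDNA copy number, i.e. what the association scans
#' adjust for.
#'
#' @param config A [sim_config()].
#' @param with_pileups If `TRUE`, reconstruct the site matrix from
#'   simulated pileups via [call_consensus()] (slower, full fidelity).
#' @param nuclear_genotypes Optional dosage matrix passed through to
#'   [simulate_counts()] for planted trans-effects.
#' @return List with `config`, `haplotypes`, `samples`, `counts`,
#'   `coverage`, `copy_numbers`, `sites`, `covariates` and (when
#'   requested) `consensus`.
#' @export
simulate_study <- function(config, with_pileups = FALSE,
                           nuclear_genotypes = NULL) {
  hap <- simulate_haplotypes(config)
  sam <- simulate_cohort(config, hap)
  counts <- simulate_counts(sam, config, nuclear_genotypes)
  coverage <- simulate_dna_coverage(sam, config$nuclear_depth,
                                    seed = config$seed)
  cn <- estimate_copy_numbers(coverage)
  consensus <- NULL
  if (with_pileups) {
    pu <- simulate_pileups(sam, hap, config)
    consensus <- vapply(pu, call_consensus, character(1))
    names(consensus) <- sam$sample_id
    sites <- build_site_matrix(consensus, hap$reference,
                               config$rdd_sites$position)
  } else {
    sites <- haplotype_site_matrix(sam, hap, config)
  }
  covariates <- data.frame(sex = sam$sex, lab = sam$lab,
                           copy_number = cn$copy_number,
                           stringsAsFactors = FALSE)
  list(config = config, haplotypes = hap, samples = sam, counts = counts,
       coverage = coverage, copy_numbers = cn, sites = sites,
       covariates = covariates, consensus = consensus)
}
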