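# Shared in-code fixtures: a small fast cohort for unit tests and a
# nested haplogroup definition used by the assignment tests.

small_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_samples = 120L,
    clade_freqs = c(L = 0.3, H = 0.4, U = 0.3),
    n_defining_snps_per_clade = 5L,
    recurrent_sites = c(1500L, 2500L),
    rdd_sites = data.frame(position = c(500L, 900L),
                           rna_allele = c("G", "A"),
                           stringsAsFactors = FALSE),
    ref_length = 3000L,
    depth_mean = 80,
    error_rate = 0,
    seed = 11L
  )
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# root -> L -> L3 -> L3b, and root -> N -> {H, U}
nested_defs <- function() {
  haplogroup_definition(data.frame(
    clade = c("L", "L", "L3", "L3", "L3b", "L3b", "L3b",
              "N", "N", "H", "H", "U"),
    parent = c("root", "root", "L", "L", "L3", "L3", "L3",
               "root", "root", "N", "N", "N"),
    position = c(100L, 200L, 300L, 400L, 500L, 600L, 700L,
                 1000L, 1100L, 1200L, 1300L, 1400L),
    derived_allele = c("G", "T", "C", "A", "G", "T", "C",
                       "A", "G", "T", "C", "A"),
    stringsAsFactors = FALSE
  ))
}

variants_of <- function(defs, clade) {
  p <- defs$path[[clade]]
  data.frame(position = p$position, alt = p$derived_allele,
             stringsAsFactors = FALSE)
}

cohort_covariates <- function(samples, copy_number = NULL) {
  data.frame(sex = samples$sex, lab = samples$lab,
             copy_number = copy_number %||% samples$true_copy_number,
             stringsAsFactors = FALSE)
}

# consensus calls + site matrix for a simulated cohort
cohort_sites <- function(samples, haplotypes, config, min_carriers = 10L,
                         min_depth = 5L, min_major_fraction = 0.7) {
  pu <- simulate_pileups(samples, haplotypes, config)
  cons <- vapply(seq_len(nrow(samples)), function(i)
    call_consensus(pu[[i]], min_depth, min_major_fraction), character(1))
  names(cons) <- samples$sample_id
  build_site_matrix(cons, haplotypes$reference,
                    config$rdd_sites$position, min_carriers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_bases_test <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
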