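## Synthetic-cohort generator.
##
## Every downstream stage of the pipeline (consensus calling, haplogroup
## assignment, normalization, eQTL scans, split-half replication,
## co-expression) is exercised on cohorts produced here, so the generator is
## first-class, tested code.  It emulates a population RNA-seq study of
## lymphoblastoid cell lines: a two-clade (African L vs out-of-Africa)
## mtDNA phylogeny with clade-defining and recurrent SNPs, negative-binomial
## read counts with haplogroup- and genotype-linked effects on chosen mtDNA
## genes plus sex/lab/copy-number covariate effects, per-sample base-count
## pileups with sequencing error and universal RNA-DNA difference (RDD)
## sites, and whole-genome DNA coverage proportional to the planted mtDNA
## copy number.

# RNG stream offsets relative to config$seed; each simulate_* draws from its
# own stream so adding one operation never perturbs another's output.
.SEED_HAPLO <- 101L
.SEED_COHORT <- 202L
.SEED_PILEUP <- 303L
.SEED_COUNTS <- 404L
.SEED_GENO <- 505L
.SEED_COVERAGE <- 606L

#' mtDNA gene annotation used by the simulator defaults
#'
#' The 13 protein-coding genes, 2 rRNA genes and 22 tRNA genes of the human
#' mitochondrial genome, with the transcript class used to separate the
#' "long RNA" (mRNA + rRNA) and tRNA datasets.
#'
#' @return A data frame with columns `gene` and `class`
#'   (`"mt-mRNA"`, `"mt-rRNA"` or `"mt-tRNA"`).
#' @export
mt_gene_table <- function() {
  mrna <- c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5",
            "MT-ND6", "MT-CO1", "MT-CO2", "MT-CO3", "MT-ATP6", "MT-ATP8",
            "MT-CYB")
  rrna <- c("MT-RNR1", "MT-RNR2")
  trna <- paste0("MT-T", c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                           "L1", "L2", "M", "N", "P", "Q", "R", "S1", "S2",
                           "T", "V", "W", "Y"))
  data.frame(
    gene = c(mrna, rrna, trna),
    class = rep(c("mt-mRNA", "mt-rRNA", "mt-tRNA"),
                c(length(mrna), length(rrna), length(trna))),
    stringsAsFactors = FALSE
  )
}

#' Default study conditions for the simulator
#'
#' `default_baseline_means()` gives the per-gene mean read counts of the 15
#' long mtDNA genes (13 mRNA + 2 rRNA); `default_planted_effects()` gives
#' the default planted signal: log-fold-change -0.5 on ten of the fifteen
#' genes in the L macro-group.
#'
#' @return A named numeric vector (means) or a data frame
#'   (`gene`, `predictor`, `lfc`).
#' @export
default_baseline_means <- function() {
  # Per-gene mean mapped-read counts spanning the range seen in bulk
  # LCL RNA-seq: tens of thousands for most protein genes up to several
  # hundred thousand for MT-CO1 and the large rRNA.
  c("MT-ND1" = 25000, "MT-ND2" = 20000, "MT-ND3" = 30000, "MT-ND4" = 60000,
    "MT-ND4L" = 15000, "MT-ND5" = 40000, "MT-ND6" = 8000,
    "MT-CO1" = 400000, "MT-CO2" = 150000, "MT-CO3" = 180000,
    "MT-ATP6" = 80000, "MT-ATP8" = 30000, "MT-CYB" = 90000,
    "MT-RNR1" = 150000, "MT-RNR2" = 450000)
}

#' @rdname default_baseline_means
#' @export
default_planted_effects <- function() {
  # Reduced expression of ten mtDNA genes on the African L background,
  # the pattern the pipeline is designed to detect and replicate.
  data.frame(
    gene = c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND6", "MT-CO1", "MT-CO2",
             "MT-ATP6", "MT-CYB", "MT-RNR1", "MT-RNR2"),
    predictor = "L",
    lfc = -0.5,
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Collects and validates all knobs of the synthetic-cohort generator.
#' Defaults describe the emulated study: 454 samples, an African
#' macro-haplogroup (clade `L`) at 20% frequency against two out-of-Africa
#' clades, seven sequencing labs, planted log-fold-change -0.5 on ten of the
#' fifteen long mtDNA genes in L samples, negative-binomial dispersion 0.1,
#' mean pileup depth 500x, and mtDNA copy numbers uniform in `[50, 500]`.
#'
#' @param n_samples Number of samples in the cohort.
#' @param clade_freqs Named numeric vector of clade frequencies; must sum
#'   to 1.  Clades whose name starts with `"L"` form the L-like macro-group.
#' @param n_defining_snps_per_clade Number of random clade-defining SNPs.
#' @param recurrent_sites Positions planted with the same derived allele on
#'   two independent clades (homoplasy), as seen at mtDNA positions 10,398
#'   and 16,129 in real phylogenies.
#' @param planted_effects Data frame with columns `gene`, `predictor`,
#'   `lfc`.  `predictor` is a macro-group (`"L"`/`"nonL"`), a clade label,
#'   or a nuclear SNP id; `lfc` is a natural-log fold change per
#'   allele/dosage unit.
#' @param nb_dispersion Negative-binomial dispersion `alpha` in
#'   `var = mu + alpha * mu^2`; `0` gives Poisson counts.
#' @param baseline_means Named positive vector of per-gene baseline mean
#'   counts.
#' @param depth_mean Mean per-position pileup depth.
#' @param error_rate Per-base sequencing error rate, in `[0, 0.5)`.
#' @param rdd_sites Data frame (`position`, `rna_allele`) of universal
#'   RNA-DNA difference sites; every sample's RNA shows the RNA allele.
#' @param copy_number_range Length-2 positive vector; true per-sample mtDNA
#'   copy numbers are uniform on this interval.
#' @param nuclear_depth Mean per-base DNA coverage of the nuclear genome.
#' @param seed Integer master seed; sub-simulators derive fixed offset
#'   streams from it.
#' @param ref_length Length of the linear mtDNA reference frame.
#' @param n_labs Number of sequencing labs.
#' @param sex_lfc,lab_lfcs,cn_log_lfc Covariate effects on log mean counts:
#'   a male-vs-female log fold change, an optional named per-lab vector of
#'   log fold changes, and a coefficient on `log(copy number / midpoint)`.
#' @param confound_lab_with_clade If `TRUE`, lab membership probabilities
#'   depend on the macro-group, creating a confounded scenario for testing
#'   covariate adjustment.
#' @param sf_log_sd Standard deviation of log-normal per-sample library
#'   size factors.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 454L,
                       clade_freqs = c(L = 0.2, H = 0.5, U = 0.3),
                       n_defining_snps_per_clade = 8L,
                       recurrent_sites = c(10398L, 16129L),
                       planted_effects = default_planted_effects(),
                       nb_dispersion = 0.1,
                       baseline_means = default_baseline_means(),
                       depth_mean = 500,
                       error_rate = 0.005,
                       rdd_sites = data.frame(
                         position = c(2619L, 5814L, 13710L),
                         rna_allele = c("G", "A", "G"),
                         stringsAsFactors = FALSE),
                       copy_number_range = c(50, 500),
                       nuclear_depth = 30,
                       seed = 1L,
                       ref_length = 16569L,
                       n_labs = 7L,
                       sex_lfc = 0,
                       lab_lfcs = NULL,
                       cn_log_lfc = 0,
                       confound_lab_with_clade = FALSE,
                       sf_log_sd = 0.15) {
  if (!is_count(n_samples) || n_samples < 1)
    stopf("n_samples must be a positive integer")
  if (is.null(names(clade_freqs)) || any(names(clade_freqs) == ""))
    stopf("clade_freqs must be a named vector")
  if (abs(sum(clade_freqs) - 1) > 1e-9)
    stopf("clade_freqs must sum to 1 (got %.6f)", sum(clade_freqs))
  if (any(clade_freqs < 0)) stopf("clade_freqs must be non-negative")
  if (error_rate < 0 || error_rate >= 0.5)
    stopf("error_rate must lie in [0, 0.5)")
  if (any(baseline_means <= 0) || is.null(names(baseline_means)))
    stopf("baseline_means must be a named vector of positive values")
  if (nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (depth_mean <= 0) stopf("depth_mean must be positive")
  if (length(copy_number_range) != 2L || any(copy_number_range <= 0) ||
      diff(copy_number_range) < 0)
    stopf("copy_number_range must be an increasing pair of positive reals")
  if (nuclear_depth <= 0) stopf("nuclear_depth must be positive")
  if (!is.data.frame(rdd_sites) ||
      !all(c("position", "rna_allele") %in% names(rdd_sites)))
    stopf("rdd_sites must be a data frame with columns position, rna_allele")
  if (any(rdd_sites$position < 1 | rdd_sites$position > ref_length))
    stopf("rdd_sites positions outside the reference frame")
  if (!all(rdd_sites$rna_allele %in% BASES))
    stopf("rdd_sites rna_allele must be one of A, C, G, T")
  if (nrow(planted_effects) &&
      !all(c("gene", "predictor", "lfc") %in% names(planted_effects)))
    stopf("planted_effects needs columns gene, predictor, lfc")
  if (any(recurrent_sites < 1 | recurrent_sites > ref_length))
    stopf("recurrent_sites outside the reference frame")

  cfg <- list(
    n_samples = as.integer(n_samples), clade_freqs = clade_freqs,
    n_defining_snps_per_clade = as.integer(n_defining_snps_per_clade),
    recurrent_sites = as.integer(recurrent_sites),
    planted_effects = planted_effects, nb_dispersion = nb_dispersion,
    baseline_means = baseline_means, depth_mean = depth_mean,
    error_rate = error_rate, rdd_sites = rdd_sites,
    copy_number_range = copy_number_range, nuclear_depth = nuclear_depth,
    seed = as.integer(seed), ref_length = as.integer(ref_length),
    n_labs = as.integer(n_labs), sex_lfc = sex_lfc, lab_lfcs = lab_lfcs,
    cn_log_lfc = cn_log_lfc,
    confound_lab_with_clade = isTRUE(confound_lab_with_clade),
    sf_log_sd = sf_log_sd
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic mtDNA reference sequence
#'
#' A deterministic random sequence on the standard 16,569-base linear
#' mitochondrial coordinate frame.  It is a synthetic stand-in with the
#' correct length and alphabet, not the rCRS itself; all coordinates in the
#' package are 1-based positions on this frame.
#'
#' @param length Reference length in bases.
#' @return A single character string over `A`, `C`, `G`, `T`.
#' @export
mt_reference <- function(length = 16569L) {
  with_seed(16569L, paste(sample(BASES, length, replace = TRUE),
                          collapse = ""))
}

#' Simulate a haplogroup phylogeny and clade haplotypes
#'
#' Plants `n_defining_snps_per_clade` random defining substitutions on each
#' clade (disjoint positions across clades) and, for each configured
#' recurrent site, the same derived allele on two independently chosen
#' clades.  Each clade's full mtDNA sequence differs from the reference by
#' exactly its defining variants.
#'
#' @param config A [sim_config()].
#' @param reference Reference sequence string; defaults to
#'   [mt_reference()] at `config$ref_length`.
#' @return A list with `definition` (a [haplogroup_definition()]),
#'   `sequences` (named character vector clade -> full sequence) and
#'   `reference`.
#' @export
simulate_haplotypes <- function(config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  reference <- reference %||% mt_reference(config$ref_length)
  if (nchar(reference) != config$ref_length)
    stopf("reference length %d does not match config ref_length %d",
          nchar(reference), config$ref_length)
  clades <- names(config$clade_freqs)
  if (length(clades) < 2L) stopf("need at least 2 clades")
  k <- config$n_defining_snps_per_clade
  ref_bases <- split_bases(reference)

  with_seed(config$seed + .SEED_HAPLO, {
    forbidden <- c(config$rdd_sites$position, config$recurrent_sites)
    pool <- setdiff(seq_len(config$ref_length), forbidden)
    if (length(pool) < k * length(clades))
      stopf("reference too short for %d defining SNPs per clade", k)
    pos_all <- if (k > 0) sample(pool, k * length(clades)) else integer()
    rows <- vector("list", length(clades))
    for (i in seq_along(clades)) {
      pos <- sort(pos_all[seq.int((i - 1L) * k + 1L, length.out = k)])
      alleles <- vapply(pos, function(p)
        sample(setdiff(BASES, ref_bases[p]), 1L), character(1))
      rows[[i]] <- data.frame(clade = rep(clades[i], k),
                              parent = rep("REF", k),
                              position = pos, derived_allele = alleles,
                              stringsAsFactors = FALSE)
    }
    defs <- do.call(rbind, rows)
    # recurrent sites: identical derived allele on two independent branches
    for (p in config$recurrent_sites) {
      allele <- sample(setdiff(BASES, ref_bases[p]), 1L)
      carriers <- sample(clades, min(2L, length(clades)))
      defs <- rbind(defs, data.frame(clade = carriers, parent = "REF",
                                     position = p, derived_allele = allele,
                                     stringsAsFactors = FALSE))
    }
    defs <- defs[order(defs$clade, defs$position), , drop = FALSE]
    rownames(defs) <- NULL

    seqs <- vapply(clades, function(cl) {
      b <- ref_bases
      d <- defs[defs$clade == cl, , drop = FALSE]
      b[d$position] <- d$derived_allele
      paste(b, collapse = "")
    }, character(1))

    list(definition = haplogroup_definition(
           defs, clades = clades,
           parents = stats::setNames(rep("REF", length(clades)), clades)),
         sequences = seqs, reference = reference)
  })
}

#' Simulate a sample table
#'
#' Draws each sample's clade from `clade_freqs`, derives the macro-group
#' (`L` for clades named `L*`, otherwise `nonL`) and population (`AFR` for
#' L-like, `EUR` otherwise), and assigns sex and sequencing lab
#' independently of clade (unless confounding is requested), a true mtDNA
#' copy number uniform on `copy_number_range`, and a log-normal library
#' size factor.
#'
#' @param config A [sim_config()].
#' @param haplotypes Output of [simulate_haplotypes()].
#' @return A data frame with one row per sample.
#' @export
simulate_cohort <- function(config, haplotypes) {
  stopifnot(inherits(config, "sim_config"))
  clades <- names(config$clade_freqs)
  n <- config$n_samples
  if (n < length(clades))
    stopf("n_samples (%d) smaller than the number of clades (%d)",
          n, length(clades))
  with_seed(config$seed + .SEED_COHORT, {
    clade <- sample(clades, n, replace = TRUE, prob = config$clade_freqs)
    macro <- ifelse(startsWith(clade, "L"), "L", "nonL")
    labs <- paste0("lab", seq_len(config$n_labs))
    if (config$confound_lab_with_clade) {
      w_l <- rev(seq_len(config$n_labs))
      w_n <- seq_len(config$n_labs)
      lab <- ifelse(macro == "L",
                    sample(labs, n, TRUE, prob = w_l / sum(w_l)),
                    sample(labs, n, TRUE, prob = w_n / sum(w_n)))
    } else {
      lab <- sample(labs, n, replace = TRUE)
    }
    data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      population = ifelse(macro == "L", "AFR", "EUR"),
      clade = clade,
      macro_group = macro,
      sex = sample(c("female", "male"), n, replace = TRUE),
      lab = lab,
      true_copy_number = stats::runif(n, config$copy_number_range[1],
                                      config$copy_number_range[2]),
      true_size_factor = exp(stats::rnorm(n, 0, config$sf_log_sd)),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate per-sample base-count pileups
#'
#' For each sample, per-position depth is Poisson(`depth_mean`); each read
#' base equals the sample's haplotype base with probability
#' `1 - error_rate`, otherwise one of the three other bases uniformly.  At
#' RDD sites every sample's reads carry the configured RNA allele
#' regardless of clade (the universal RNA-DNA differences).
#'
#' @param samples Sample table from [simulate_cohort()].
#' @param haplotypes Output of [simulate_haplotypes()].
#' @param config A [sim_config()].
#' @return Named list (by sample id) of integer matrices
#'   `positions x 4` with columns `A`, `C`, `G`, `T`.
#' @export
simulate_pileups <- function(samples, haplotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  defs <- haplotypes$definition
  collide <- intersect(config$rdd_sites$position, defs$table$position)
  if (length(collide))
    stopf("RDD position(s) %s collide with clade-defining positions",
          paste(collide, collapse = ", "))
  L <- config$ref_length
  rdd_pos <- config$rdd_sites$position
  rdd_idx <- match(config$rdd_sites$rna_allele, BASES)

  clade_idx <- lapply(haplotypes$sequences, function(s) {
    idx <- match(split_bases(s), BASES)
    idx[rdd_pos] <- rdd_idx
    idx
  })

  with_seed(config$seed + .SEED_PILEUP, {
    out <- vector("list", nrow(samples))
    names(out) <- samples$sample_id
    for (i in seq_len(nrow(samples))) {
      truth <- clade_idx[[samples$clade[i]]]
      depth <- stats::rpois(L, config$depth_mean)
      err <- stats::rbinom(L, depth, config$error_rate)
      e1 <- stats::rbinom(L, err, 1 / 3)
      e2 <- stats::rbinom(L, err - e1, 1 / 2)
      e3 <- err - e1 - e2
      m <- matrix(0L, nrow = L, ncol = 4L,
                  dimnames = list(NULL, BASES))
      rowi <- seq_len(L)
      m[cbind(rowi, truth)] <- depth - err
      o1 <- truth %% 4L + 1L
      o2 <- o1 %% 4L + 1L
      o3 <- o2 %% 4L + 1L
      m[cbind(rowi, o1)] <- m[cbind(rowi, o1)] + e1
      m[cbind(rowi, o2)] <- m[cbind(rowi, o2)] + e2
      m[cbind(rowi, o3)] <- m[cbind(rowi, o3)] + e3
      out[[i]] <- m
    }
    out
  })
}

# Resolve planted/covariate effects into a per-gene, per-sample log-scale
# offset matrix.
effect_log_matrix <- function(samples, config, nuclear_genotypes = NULL) {
  genes <- names(config$baseline_means)
  n <- nrow(samples)
  eff <- matrix(0, nrow = length(genes), ncol = n,
                dimnames = list(genes, samples$sample_id))
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    for (r in seq_len(nrow(pe))) {
      g <- pe$gene[r]
      if (!g %in% genes) stopf("planted effect on unknown gene '%s'", g)
      pred <- pe$predictor[r]
      x <- if (pred %in% c(samples$macro_group)) {
        as.numeric(samples$macro_group == pred)
      } else if (pred %in% samples$clade) {
        as.numeric(samples$clade == pred)
      } else if (!is.null(nuclear_genotypes) &&
                 pred %in% rownames(nuclear_genotypes)) {
        as.numeric(nuclear_genotypes[pred, samples$sample_id])
      } else {
        stopf("planted predictor '%s' matches no macro-group, clade or SNP",
              pred)
      }
      eff[g, ] <- eff[g, ] + pe$lfc[r] * x
    }
  }
  if (config$sex_lfc != 0)
    eff <- sweep(eff, 2, config$sex_lfc * (samples$sex == "male"), "+")
  if (!is.null(config$lab_lfcs)) {
    lab_eff <- config$lab_lfcs[samples$lab]
    lab_eff[is.na(lab_eff)] <- 0
    eff <- sweep(eff, 2, lab_eff, "+")
  }
  if (config$cn_log_lfc != 0) {
    mid <- mean(config$copy_number_range)
    eff <- sweep(eff, 2,
                 config$cn_log_lfc * log(samples$true_copy_number / mid),
                 "+")
  }
  eff
}

#' Simulate a gene-by-sample count matrix
#'
#' Counts are negative binomial with mean
#' `baseline(gene) * size_factor(sample) * exp(sum of active log effects)`
#' and variance `mu + alpha * mu^2`; dispersion 0 gives Poisson counts.
#' Active effects are the planted haplogroup/clade/nuclear-SNP log-fold
#' changes and the configured sex/lab/copy-number covariate effects.
#'
#' @param samples Sample table from [simulate_cohort()].
#' @param config A [sim_config()].
#' @param nuclear_genotypes Optional dosage matrix from
#'   [simulate_nuclear_genotypes()], required when a planted predictor is a
#'   nuclear SNP id.
#' @return Integer matrix genes x samples; the resolved per-gene,
#'   per-sample log-effect matrix is attached as attribute `"log_effects"`
#'   for use as a test oracle.
#' @export
simulate_counts <- function(samples, config, nuclear_genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- names(config$baseline_means)
  eff <- effect_log_matrix(samples, config, nuclear_genotypes)
  mu <- config$baseline_means * exp(eff)
  mu <- sweep(mu, 2, samples$true_size_factor, "*")
  with_seed(config$seed + .SEED_COUNTS, {
    cnt <- if (config$nb_dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    counts <- matrix(cnt, nrow = length(genes),
                     dimnames = list(genes, samples$sample_id))
    attr(counts, "log_effects") <- eff
    counts
  })
}

#' Simulate diploid nuclear genotype dosages
#'
#' SNP dosages 0/1/2 drawn binomially with the given minor-allele
#' frequency, i.e. in Hardy-Weinberg proportions.
#'
#' @param samples Sample table.
#' @param n_snps Number of SNPs.
#' @param maf Minor-allele frequency (scalar or length `n_snps`), in
#'   `(0, 0.5]`.
#' @param seed Integer seed.
#' @param snp_ids Optional SNP names (default `snp_0001`, ...), so planted
#'   trans-effects can reference them.
#' @return Integer matrix SNPs x samples with attribute `ploidy =
#'   "diploid"`.
#' @export
simulate_nuclear_genotypes <- function(samples, n_snps = 50L, maf = 0.3,
                                       seed = 1L, snp_ids = NULL) {
  if (any(maf <= 0 | maf > 0.5)) stopf("maf must lie in (0, 0.5]")
  if (!is_count(n_snps) || n_snps < 1) stopf("n_snps must be positive")
  maf <- rep_len(maf, n_snps)
  snp_ids <- snp_ids %||% sprintf("snp_%04d", seq_len(n_snps))
  n <- nrow(samples)
  with_seed(seed + .SEED_GENO, {
    g <- matrix(stats::rbinom(n_snps * n, 2L, rep(maf, times = n)),
                nrow = n_snps,
                dimnames = list(snp_ids, samples$sample_id))
    attr(g, "ploidy") <- "diploid"
    g
  })
}

#' Simulate DNA coverage summaries
#'
#' Per sample: total mtDNA read coverage over the first 16,499 reference
#' bases is Poisson with mean `nuclear_depth * true_copy_number` per base,
#' and each of 22 autosomal 100,000-base windows has Poisson coverage with
#' per-base mean `nuclear_depth` - so the mt/autosome coverage ratio equals
#' the planted copy number in expectation.
#'
#' @param samples Sample table with `true_copy_number`.
#' @param nuclear_depth Mean per-base nuclear coverage (> 0).
#' @param seed Integer seed.
#' @param noise If `FALSE`, return noiseless expectations.
#' @param mt_length Number of mtDNA bases averaged (default 16,499).
#' @param window_length Autosomal window length in bases.
#' @return Data frame with `sample_id`, `mt_mean` and columns
#'   `auto_chr1` ... `auto_chr22` of window mean coverages.
#' @export
simulate_dna_coverage <- function(samples, nuclear_depth = 30, seed = 1L,
                                  noise = TRUE, mt_length = 16499L,
                                  window_length = 100000L) {
  if (nuclear_depth <= 0) stopf("nuclear_depth must be positive")
  n <- nrow(samples)
  with_seed(seed + .SEED_COVERAGE, {
    if (noise) {
      mt_mean <- stats::rpois(n, nuclear_depth * samples$true_copy_number *
                                   mt_length) / mt_length
      auto <- matrix(stats::rpois(n * 22L, nuclear_depth * window_length),
                     nrow = n) / window_length
    } else {
      mt_mean <- nuclear_depth * samples$true_copy_number
      auto <- matrix(nuclear_depth, nrow = n, ncol = 22L)
    }
    colnames(auto) <- paste0("auto_chr", 1:22)
    cbind(data.frame(sample_id = samples$sample_id, mt_mean = mt_mean,
                     stringsAsFactors = FALSE),
          as.data.frame(auto))
  })
}
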