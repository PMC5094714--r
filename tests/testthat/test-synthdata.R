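test_that("clade haplotypes differ from the reference by exactly their defining variants", {
  cfg <- small_config(clade_freqs = c(L = 0.5, H = 0.5),
                      n_defining_snps_per_clade = 3L,
                      recurrent_sites = integer())
  hap <- simulate_haplotypes(cfg)
  ref <- split_bases_test(hap$reference)
  diffs <- lapply(hap$sequences, function(s) which(split_bases_test(s) != ref))
  expect_equal(lengths(diffs), c(L = 3L, H = 3L))
  expect_length(intersect(diffs$L, diffs$H), 0L)
  for (cl in c("L", "H")) {
    def <- hap$definition$table
    expect_setequal(diffs[[cl]], def$position[def$clade == cl])
  }
})

test_that("zero defining SNPs leaves every clade identical to the reference", {
  cfg <- small_config(n_defining_snps_per_clade = 0L,
                      recurrent_sites = integer())
  hap <- simulate_haplotypes(cfg)
  expect_true(all(hap$sequences == hap$reference))
})

test_that("recurrent sites carry one derived allele on two independent clades", {
  cfg <- small_config()
  hap <- simulate_haplotypes(cfg)
  tab <- hap$definition$table
  for (p in cfg$recurrent_sites) {
    rows <- tab[tab$position == p, ]
    expect_equal(nrow(rows), 2L)
    expect_equal(length(unique(rows$derived_allele)), 1L)
    expect_equal(length(unique(rows$clade)), 2L)
  }
})

test_that("simulators are deterministic in the seed and sensitive to it", {
  cfg1 <- small_config(seed = 5L, error_rate = 0.01)
  cfg2 <- small_config(seed = 6L, error_rate = 0.01)
  h1a <- simulate_haplotypes(cfg1); h1b <- simulate_haplotypes(cfg1)
  h2 <- simulate_haplotypes(cfg2)
  expect_identical(h1a, h1b)
  expect_false(identical(h1a$definition$table$position,
                         h2$definition$table$position))
  s1a <- simulate_cohort(cfg1, h1a); s1b <- simulate_cohort(cfg1, h1b)
  expect_identical(s1a, s1b)
  expect_identical(simulate_counts(s1a, cfg1), simulate_counts(s1b, cfg1))
  p1a <- simulate_pileups(s1a[1:3, ], h1a, cfg1)
  p1b <- simulate_pileups(s1b[1:3, ], h1b, cfg1)
  expect_identical(p1a, p1b)
  g1 <- simulate_nuclear_genotypes(s1a, 10, 0.3, seed = 1)
  expect_identical(g1, simulate_nuclear_genotypes(s1a, 10, 0.3, seed = 1))
  expect_false(identical(g1, simulate_nuclear_genotypes(s1a, 10, 0.3,
                                                        seed = 2)))
})

test_that("cohort clade frequencies match the configured mixture", {
  cfg <- small_config(n_samples = 1000L,
                      clade_freqs = c(L = 0.2, H = 0.8), seed = 21L)
  hap <- simulate_haplotypes(cfg)
  sam <- simulate_cohort(cfg, hap)
  p_hat <- mean(sam$clade == "L")
  sd3 <- 3 * sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(p_hat - 0.2), sd3)
  expect_true(all(sam$macro_group[sam$clade == "L"] == "L"))
  expect_false(any(duplicated(sam$sample_id)))

  cfg_all_l <- small_config(clade_freqs = c(L = 0.7, L3 = 0.3))
  sam_l <- simulate_cohort(cfg_all_l, simulate_haplotypes(cfg_all_l))
  expect_true(all(sam_l$macro_group == "L"))
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(clade_freqs = c(L = 0.4, H = 0.5)), "sum to 1")
  expect_error(small_config(error_rate = 0.6), "error_rate")
  expect_error(small_config(baseline_means = c(A = -1)), "positive")
  cfg <- small_config(clade_freqs = c(L = 0.3, H = 0.4, U = 0.3),
                      n_samples = 2L)
  expect_error(simulate_cohort(cfg, simulate_haplotypes(cfg)), "smaller")
  sam <- simulate_cohort(small_config(), simulate_haplotypes(small_config()))
  expect_error(simulate_nuclear_genotypes(sam, 5, maf = 0), "maf")
  expect_error(simulate_dna_coverage(sam, nuclear_depth = 0), "positive")
})

test_that("error-free pileups are unanimous for the haplotype base and RDD sites dominate", {
  cfg <- small_config(n_samples = 6L, depth_mean = 50)
  hap <- simulate_haplotypes(cfg)
  sam <- simulate_cohort(cfg, hap)
  pu <- simulate_pileups(sam, hap, cfg)
  for (i in seq_len(nrow(sam))) {
    m <- pu[[i]]
    expect_true(all(rowSums(m > 0) <= 1))  # one base per position
    modal <- c("A", "C", "G", "T")[max.col(m)]
    truth <- split_bases_test(hap$sequences[[sam$clade[i]]])
    non_rdd <- setdiff(which(rowSums(m) > 0), cfg$rdd_sites$position)
    expect_identical(modal[non_rdd], truth[non_rdd])
    for (r in seq_len(nrow(cfg$rdd_sites))) {
      p <- cfg$rdd_sites$position[r]
      if (sum(m[p, ]) > 0)
        expect_identical(modal[p], cfg$rdd_sites$rna_allele[r])
    }
  }
})

test_that("an RDD position colliding with a defining site is rejected", {
  cfg <- small_config()
  hap <- simulate_haplotypes(cfg)
  sam <- simulate_cohort(cfg, hap)
  bad <- cfg
  bad$rdd_sites <- data.frame(position = hap$definition$table$position[1],
                              rna_allele = "G")
  expect_error(simulate_pileups(sam, hap, bad), "collide")
})

test_that("planted log-fold-changes move group means as configured", {
  cfg <- small_config(
    n_samples = 400L, clade_freqs = c(L = 0.5, H = 0.5),
    planted_effects = data.frame(gene = "MT-ND2", predictor = "L",
                                 lfc = -0.5),
    seed = 31L)
  hap <- simulate_haplotypes(cfg)
  sam <- simulate_cohort(cfg, hap)
  cnt <- simulate_counts(sam, cfg)
  # undo the library size factor to isolate the planted effect
  adj <- sweep(cnt, 2, sam$true_size_factor, "/")
  ratio <- mean(adj["MT-ND2", sam$macro_group == "L"]) /
    mean(adj["MT-ND2", sam$macro_group == "nonL"])
  expect_lt(abs(ratio - exp(-0.5)), 0.1)
  # unplanted gene: ratio near 1
  ratio0 <- mean(adj["MT-ND5", sam$macro_group == "L"]) /
    mean(adj["MT-ND5", sam$macro_group == "nonL"])
  expect_lt(abs(ratio0 - 1), 0.15)
})

test_that("dispersion zero gives Poisson-like variance", {
  cfg <- small_config(n_samples = 500L, nb_dispersion = 0, sf_log_sd = 0,
                      baseline_means = c(G1 = 100), planted_effects =
                        data.frame(gene = character(),
                                   predictor = character(),
                                   lfc = numeric()))
  hap <- simulate_haplotypes(cfg)
  sam <- simulate_cohort(cfg, hap)
  cnt <- simulate_counts(sam, cfg)
  vm <- stats::var(cnt["G1", ]) / mean(cnt["G1", ])
  expect_lt(abs(vm - 1), 0.35)
  # and a clearly super-Poisson check at dispersion 0.1
  cfg2 <- small_config(n_samples = 500L, nb_dispersion = 0.1, sf_log_sd = 0,
                       baseline_means = c(G1 = 100), planted_effects =
                         cfg$planted_effects)
  cnt2 <- simulate_counts(simulate_cohort(cfg2, hap), cfg2)
  expect_gt(stats::var(cnt2["G1", ]) / mean(cnt2["G1", ]), 5)
})

test_that("nuclear genotypes follow Hardy-Weinberg proportions", {
  cfg <- small_config(n_samples = 4000L)
  sam <- simulate_cohort(cfg, simulate_haplotypes(cfg))
  g <- simulate_nuclear_genotypes(sam, n_snps = 1L, maf = 0.5, seed = 3L)
  freq <- tabulate(g[1, ] + 1L, 3L) / ncol(g)
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 3 * sqrt(0.25 / 4000))
  expect_identical(attr(g, "ploidy"), "diploid")
})

test_that("noiseless DNA coverage equals depth times copy number", {
  cfg <- small_config(n_samples = 5L)
  sam <- simulate_cohort(cfg, simulate_haplotypes(cfg))
  sam$true_copy_number <- rep(100, 5)
  cov <- simulate_dna_coverage(sam, nuclear_depth = 10, noise = FALSE)
  expect_equal(cov$mt_mean, rep(1000, 5))
  expect_true(all(cov[, grep("^auto_", names(cov))] == 10))
})
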