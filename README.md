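# mteqtl

Haplogroup-aware analysis of mitochondrial gene expression from RNA-seq.

Because human mtDNA is transcribed as strand-wide polycistrons, bulk
RNA-seq covers the whole 16,569-base mitochondrial genome. `mteqtl`
turns that fact into a pipeline for population-scale cohorts:

1. **Consensus & variants** — majority-rule reconstruction of each
   sample's mtDNA sequence from base-count pileups, substitution calls
   against the reference with universal RNA–DNA difference (RDD) sites
   masked, and a cohort polymorphic-site matrix (≥10 carriers, ≤3
   alleles per site).
2. **Haplogroups & phylogeny** — clade assignment by scoring cumulative
   defining-variant paths (recurrent variants supported), p-distances
   with pairwise deletion, neighbor joining, and monophyly checks.
3. **Normalization** — median-of-ratios size factors
   (`factor(s) = median_g count_gs / geometric-mean_g`) and a
   gene-presence filter (reads in > 90% of samples).
4. **eQTL scans** — per (site, allele, gene) ordinary least squares on
   normalized expression with sex, lab and mtDNA copy-number covariates:
   `y_g = β0 + β1·1[allele] + γ'·covariates + ε`, two-sided t tests,
   Bonferroni-corrected per scan family; stratified per-population scans
   and a background-masking contrast with a Wald heterogeneity test.
5. **Split-half replication** — repeated re-division of the cohort into
   two sex- and population-matched halves, everything recomputed per
   half; associations count as replicated only when Bonferroni-significant
   in *both* halves, and genes pass when they replicate in > 60% of
   divisions.
6. **Copy number** — mean mtDNA coverage (positions 1–16,499) over the
   mean of 22 fixed autosomal 100-kb windows, compared between groups by
   Kruskal–Wallis.
7. **Co-expression screen** — Pearson correlation of every nuclear gene
   against the 15 long mtDNA genes, a two-stage differential filter
   (L vs non-L, covariate-adjusted), direction summaries, and
   hypergeometric fold-enrichment statistics for user-supplied
   annotations.

A first-class synthetic-cohort generator (`sim_config()`,
`simulate_study()` and friends) emulates the statistical structure such
a study assumes — a two-clade L vs non-L phylogeny with defining and
recurrent SNPs, negative-binomial counts with planted haplogroup and
covariate effects, pileups with sequencing error and RDD sites, and DNA
coverage proportional to planted copy number — so the entire pipeline is
testable end to end without external data.

## Worked example

```r
library(mteqtl)

cfg <- sim_config(
  n_samples = 400,
  baseline_means = c(default_baseline_means(),
                     setNames(rep(2000, 100), sprintf("NUC_%03d", 1:100))),
  seed = 2024)           # 10 of 15 mtDNA genes planted at lfc -0.5 in L
study <- simulate_study(cfg)

norm <- normalize_counts(study$counts, size_factors(study$counts))
scan <- eqtl_scan(norm, study$sites, study$covariates)
sig  <- subset(scan, p < attr(scan, "bonferroni"))
sort(unique(sig$gene))
#>  [1] "MT-ATP6" "MT-CO1"  "MT-CO2"  "MT-CYB"  "MT-ND1"  "MT-ND2"  "MT-ND3"
#>  [8] "MT-ND6"  "MT-RNR1" "MT-RNR2" "NUC_013"

rep_report <- run_replicates(study$counts, study$sites, study$covariates,
                             study$samples, n_replicates = 50, seed = 2024)
consistency_report(rep_report, cutoff = 0.6)$gene
#>  [1] "MT-ATP6" "MT-CO1"  "MT-CO2"  "MT-CYB"  "MT-ND1"  "MT-ND2"  "MT-ND3"
#>  [8] "MT-ND6"  "MT-RNR1" "MT-RNR2"
```

The pooled scan (2,990 tests; Bonferroni threshold 1.67e-5) recovers all
ten genes planted with reduced expression on the L background — plus one
marginal false positive among the 100 null nuclear genes (`NUC_013`, a
consequence of the small compositional bias median-of-ratios
normalization acquires when 10 of 115 genes truly shift; see the
vignette). The split-half replication stage then does exactly the job it
exists for: across 50 stratified re-divisions only the ten planted genes
are Bonferroni-significant in both halves in more than 60% of divisions,
and the false positive is filtered out.

The methods vignette (`vignettes/mtdna-expression-pipeline.Rmd`) details
the model, parameter defaults, numerical choices and limitations.

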