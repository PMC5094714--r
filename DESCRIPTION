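Package: mteqtl
Title: Haplogroup-Aware Mitochondrial DNA Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs per-sample mitochondrial DNA consensus sequences from
    RNA-seq base-count pileups, assigns mtDNA haplogroups from defining
    variants, and tests mitochondrial and nuclear variants for association
    with mtDNA gene expression. Includes median-of-ratios library-size
    normalization, mtDNA copy-number estimation from DNA coverage ratios, a
    stratified split-half replication procedure for certifying
    haplogroup-associated genes, a Pearson co-expression screen with a
    two-stage differential filter and hypergeometric enrichment statistics,
    and a synthetic-cohort generator that emulates the statistical structure
    of population-scale lymphoblastoid RNA-seq studies so that the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
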