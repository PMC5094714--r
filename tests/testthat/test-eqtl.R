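# brute-force OLS oracle: normal equations + t CDF, written independently
# of the package's QR path
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tv <- unname(beta[2] / se[2])
  list(effect = unname(beta[2]), se = unname(se[2]), t = tv,
       p = 2 * pt(-abs(tv), df), df = df)
}

test_that("site filters enforce the carrier and major-frequency boundaries", {
  mk_site <- function(n_minor, n_total, minor = "G", major = "A") {
    c(rep(minor, n_minor), rep(major, n_total - n_minor))
  }
  # carrier boundary in a 100-sample cohort (major frequency passes)
  G1 <- rbind(nine = mk_site(9, 100), ten = mk_site(10, 100))
  attr(G1, "ploidy") <- "haploid"
  kept1 <- rownames(site_filters(G1, min_carriers = 10,
                                 max_major_freq = 0.95))
  expect_false("nine" %in% kept1)   # 9 carriers < 10
  expect_true("ten" %in% kept1)
  # major-allele frequency boundary in the 454-sample cohort; a minor
  # shared by only 9 of 454 fails both rules
  G2 <- rbind(nine454 = mk_site(9, 454), at95 = mk_site(23, 454),
              over95 = mk_site(22, 454))
  attr(G2, "ploidy") <- "haploid"
  kept2 <- rownames(site_filters(G2, min_carriers = 10,
                                 max_major_freq = 0.95))
  expect_false("nine454" %in% kept2)
  expect_true("at95" %in% kept2)    # major 431/454 = 94.9% <= 95%
  expect_false("over95" %in% kept2)  # major 432/454 = 95.2% > 95%
})

test_that("tri-allelic sites keep both minors testable", {
  g <- c(rep("A", 300), rep("C", 100), rep("G", 54))
  G <- matrix(g, nrow = 1, dimnames = list("tri", NULL))
  attr(G, "ploidy") <- "haploid"
  expect_equal(nrow(site_filters(G)), 1L)
  designs <- encode_design(g, ploidy = "haploid")
  expect_setequal(vapply(designs, `[[`, character(1), "allele"),
                  c("C", "G"))
})

test_that("diploid dosage sites are filtered on carriers and allele frequency", {
  G <- rbind(common = c(rep(0L, 50), rep(1L, 30), rep(2L, 20)),
             rare = c(rep(0L, 95), rep(1L, 5)))
  attr(G, "ploidy") <- "diploid"
  kept <- site_filters(G, min_carriers = 10, max_major_freq = 0.95)
  expect_identical(rownames(kept), "common")
})

test_that("degenerate designs are skipped or rejected informatively", {
  g <- rep("A", 20)
  expect_length(encode_design(g, ploidy = "haploid"), 0L)
  cov <- data.frame(lab = rep("lab1", 20), sex = rep(c("m", "f"), 10))
  g2 <- rep(c("A", "G"), each = 10)
  d <- encode_design(g2, cov, ploidy = "haploid")[[1]]
  expect_false("lablab1" %in% colnames(d$X))  # constant lab dropped
  expect_true(any(grepl("sex", colnames(d$X))))
  # collinear column triggers an error naming it
  X <- cbind(`(Intercept)` = 1, allele = rep(0:1, 10),
             dup = rep(0:1, 10))
  expect_error(mteqtl:::fit_ols_multi(X, rnorm(20)), "dup")
})

test_that("a noiseless linear relation is recovered exactly", {
  x <- rep(c(0, 1), each = 10)
  y <- 2 * x
  d <- encode_design(ifelse(x == 1, "G", "A"), ploidy = "haploid")[[1]]
  fit <- fit_linear(y, d)
  expect_equal(fit$effect, 2, tolerance = 1e-12)
  expect_lt(fit$p, 1e-200)
})

test_that("fit_linear matches the normal-equations oracle on a fixed fixture", {
  y <- c(3.1, 4.0, 2.2, 5.5, 4.1, 6.3, 5.9, 7.2, 6.8, 8.0)
  allele <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  covar <- c(1.2, 0.5, -0.3, 2.0, 0.8, -0.1, 1.5, 0.4, 0.9, -0.7)
  g <- ifelse(allele == 1, "G", "A")
  d <- encode_design(g, data.frame(c1 = covar), ploidy = "haploid")[[1]]
  fit <- fit_linear(y, d)
  orc <- ols_oracle(y, cbind(1, allele, covar))
  expect_equal(fit$effect, orc$effect, tolerance = 1e-10)
  expect_equal(fit$se, orc$se, tolerance = 1e-10)
  expect_equal(fit$t, orc$t, tolerance = 1e-10)
  expect_equal(fit$p, orc$p, tolerance = 1e-10)
  expect_equal(fit$df, orc$df)
})

test_that("null p-values are uniform", {
  set.seed(19)
  n <- 40
  g <- ifelse(rbinom(n, 1, 0.4) == 1, "G", "A")
  d <- encode_design(g, ploidy = "haploid")[[1]]
  ps <- replicate(800, fit_linear(rnorm(n), d)$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the Bonferroni threshold reproduces the published arithmetic", {
  expect_equal(signif(bonferroni_threshold(0.05, 7665), 3), 6.52e-6)
  # 0.05 / (15 x 63,662) = 5.236e-8, printed truncated as "p < 5.23e-8"
  expect_equal(bonferroni_threshold(0.05, 15 * 63662), 5.23e-8,
               tolerance = 0.002)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("the scan equals fit_linear on a single site-gene pair and books its family", {
  set.seed(23)
  n <- 60
  g <- c(rep("G", 20), rep("A", 40))
  G <- matrix(g, nrow = 1, dimnames = list("m123", NULL))
  attr(G, "ploidy") <- "haploid"
  y <- rnorm(n, 10 + 2 * (g == "G"))
  expr <- matrix(y, nrow = 1, dimnames = list("GENE1", NULL))
  cov <- data.frame(sex = rep(c("m", "f"), 30))
  scan <- eqtl_scan(expr, G, cov)
  d <- encode_design(g, cov, ploidy = "haploid")[[1]]
  fit <- fit_linear(y, d)
  expect_equal(scan$effect, fit$effect)
  expect_equal(scan$p, fit$p)
  expect_equal(attr(scan, "n_tests"), nrow(scan))
  expect_equal(attr(scan, "bonferroni"), 0.05 / nrow(scan))
  # monomorphic genotypes produce an empty scan
  G0 <- matrix("A", nrow = 1, ncol = n, dimnames = list("m1", NULL))
  attr(G0, "ploidy") <- "haploid"
  scan0 <- eqtl_scan(expr, G0, cov)
  expect_equal(nrow(scan0), 0L)
})

test_that("covariate adjustment neutralizes a lab confounder", {
  # lab membership is confounded with the tested allele, and each gene
  # carries its own lab batch effect; the allele itself has no effect.
  set.seed(61)
  n <- 300L
  n_genes <- 300L
  lab <- sample(paste0("lab", 1:4), n, TRUE)
  p_g <- ifelse(lab %in% c("lab1", "lab2"), 0.55, 0.1)
  g <- ifelse(rbinom(n, 1, p_g) == 1, "G", "A")
  G <- matrix(g, nrow = 1, dimnames = list("m100", NULL))
  attr(G, "ploidy") <- "haploid"
  lab_shift <- matrix(rnorm(n_genes * 4, 0, 0.6), ncol = 4,
                      dimnames = list(NULL, paste0("lab", 1:4)))
  expr <- matrix(rnorm(n_genes * n), nrow = n_genes,
                 dimnames = list(sprintf("g%03d", 1:n_genes), NULL)) +
    lab_shift[, lab]
  cov_lab <- data.frame(lab = lab)
  scan_adj <- eqtl_scan(expr, G, cov_lab, min_carriers = 5)
  scan_raw <- eqtl_scan(expr, G, NULL, min_carriers = 5)
  rate_adj <- mean(scan_adj$p < 0.05)
  rate_raw <- mean(scan_raw$p < 0.05)
  expect_lt(rate_adj, 0.05 + 3 * sqrt(0.05 * 0.95 / n_genes))
  expect_gt(rate_raw, 0.15)
})

test_that("stratified scans find stratum-specific effects and skip small strata", {
  set.seed(71)
  n <- 200
  strata <- rep(c("AFR", "EUR"), each = n / 2)
  g <- sample(c("A", "G"), n, TRUE)
  G <- matrix(g, nrow = 1, dimnames = list("s1", NULL))
  attr(G, "ploidy") <- "haploid"
  y <- rnorm(n) + ifelse(strata == "AFR" & g == "G", 2, 0)
  expr <- matrix(y, nrow = 1, dimnames = list("GENE", NULL))
  res <- stratified_scan(expr, G, NULL, strata)
  expect_setequal(names(res), c("AFR", "EUR"))
  expect_lt(res$AFR$p[1], attr(res$AFR, "bonferroni"))
  expect_gt(res$EUR$p[1], 0.001)
  expect_match(res$AFR$family[1], "stratified:AFR")
  # a single stratum equals the unstratified scan
  res1 <- stratified_scan(expr, G, NULL, rep("ALL", n))
  plain <- eqtl_scan(expr, G, NULL)
  expect_equal(res1$ALL$p, plain$p)
  # too-small stratum skipped with a warning
  expect_warning(
    res2 <- stratified_scan(expr, G, NULL,
                            c(rep("big", n - 5), rep("tiny", 5))),
    "tiny")
  expect_false("tiny" %in% names(res2))
})

test_that("background contrast reports pooled, per-background and heterogeneity", {
  set.seed(83)
  n_bg <- 150
  backgrounds <- rep(c("AFR", "EUR"), each = n_bg)
  g <- rep(rep(c("T", "C"), each = n_bg / 2), 2)
  delta <- 1.5
  y <- rnorm(2 * n_bg, sd = 0.8) +
    ifelse(backgrounds == "AFR", delta, -delta) * (g == "C")
  bc <- background_contrast(y, g, backgrounds)
  expect_equal(nrow(bc$per_background), 2L)
  expect_true(all(bc$per_background$p < 1e-6))
  expect_gt(bc$pooled$p, 0.001)        # masked when pooled
  expect_lt(bc$heterogeneity$p, 1e-6)
  # identical effects: heterogeneity should not fire
  y2 <- rnorm(2 * n_bg, sd = 0.8) + delta * (g == "C")
  bc2 <- background_contrast(y2, g, backgrounds)
  expect_gt(bc2$heterogeneity$p, 1e-4)
  # a background lacking one allele is excluded and flagged
  g3 <- g; g3[backgrounds == "EUR"] <- "T"
  bc3 <- background_contrast(y, g3, backgrounds, allele = "C")
  expect_identical(bc3$excluded, "EUR")
  expect_null(bc3$heterogeneity)
  expect_equal(bc3$pooled$effect, bc3$per_background$effect[1])
})
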