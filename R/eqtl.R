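## SNP-expression association scans.
##
## Each association is an ordinary-least-squares fit of one gene's
## (normalized) expression on an allele predictor plus covariates (sex,
## sequencing lab expanded to indicator columns with a dropped reference
## level, mtDNA copy number).  Haploid mtDNA sites are tested one minor
## allele at a time against all other alleles (a 1-df indicator); diploid
## nuclear SNPs enter as additive 0/1/2 dosages.  Multiple testing is
## controlled per scan family by Bonferroni correction.

#' Site filters for a genotype matrix
#'
#' A site is retained iff at least one non-major allele has at least
#' `min_carriers` carriers and the major-allele frequency does not exceed
#' `max_major_freq`.  `N`/missing entries are excluded from the frequency
#' denominators.  For diploid dosage rows, carriers of the minor allele
#' are samples with at least one copy, and allele frequencies are computed
#' from the dosages.
#'
#' @param genotypes Character matrix (haploid alleles, `N` = missing) or
#'   numeric matrix (diploid dosages 0/1/2), sites x samples, with
#'   attribute `ploidy` (`"haploid"` is assumed for character input).
#' @param min_carriers Minimum carriers of some non-major allele
#'   (default 10).
#' @param max_major_freq Maximum major-allele frequency (default 0.95).
#' @return The filtered genotype matrix (possibly zero rows), `ploidy`
#'   attribute preserved.
#' @export
site_filters <- function(genotypes, min_carriers = 10L,
                         max_major_freq = 0.95) {
  ploidy <- genotype_ploidy(genotypes)
  keep <- vapply(seq_len(nrow(genotypes)), function(i) {
    g <- genotypes[i, ]
    if (ploidy == "haploid") {
      tab <- sort(table(g[g != "N"]), decreasing = TRUE)
      if (length(tab) < 2L) return(FALSE)
      major_freq <- tab[1L] / sum(tab)
      any(tab[-1L] >= min_carriers) && major_freq <= max_major_freq
    } else {
      d <- g[!is.na(g)]
      if (!length(d)) return(FALSE)
      p_alt <- mean(d) / 2
      major_freq <- max(p_alt, 1 - p_alt)
      carriers <- if (p_alt <= 0.5) sum(d > 0) else sum(d < 2)
      carriers >= min_carriers && major_freq <= max_major_freq
    }
  }, logical(1))
  out <- genotypes[keep, , drop = FALSE]
  attr(out, "ploidy") <- ploidy
  out
}

genotype_ploidy <- function(genotypes) {
  attr(genotypes, "ploidy") %||%
    if (is.character(genotypes)) "haploid" else "diploid"
}

# Covariate data frame -> numeric columns (factor expansion, reference
# level dropped, constant columns removed).  Returns NULL when nothing
# informative remains.
covariate_columns <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0L) return(NULL)
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates)) stopf("covariates contain missing values")
  keep <- vapply(covariates, function(x) length(unique(x)) > 1L, logical(1))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0L) return(NULL)
  chr <- vapply(covariates, function(x) is.character(x) || is.logical(x),
                logical(1))
  covariates[chr] <- lapply(covariates[chr], factor)
  stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
}

#' Encode the regression design(s) for one site
#'
#' Haploid sites produce one design per minor allele: a 0/1 indicator of
#' that allele against all other called alleles, with `N` samples removed.
#' Diploid sites produce a single additive-dosage design.  Covariates are
#' appended after factor expansion; covariate columns that become constant
#' on the retained samples are dropped.  Designs whose predictor is
#' constant after missing-data removal are skipped (returned with
#' `skipped` set and a reason).
#'
#' @param genotype Genotype vector for one site (character alleles or
#'   numeric dosages), named by sample when available.
#' @param covariates Optional data frame of covariates (one row per
#'   sample, aligned with `genotype`).
#' @param ploidy `"haploid"` or `"diploid"`; default guessed from type.
#' @return List of designs; each has `allele`, `rows` (logical vector of
#'   used samples), `X` (model matrix: intercept, predictor, covariates),
#'   `skipped` and `reason`.
#' @export
encode_design <- function(genotype, covariates = NULL, ploidy = NULL) {
  ploidy <- ploidy %||%
    (if (is.character(genotype)) "haploid" else "diploid")
  designs <- list()
  if (ploidy == "haploid") {
    tab <- sort(table(genotype[genotype != "N"]), decreasing = TRUE)
    minors <- names(tab)[-1L]
    for (al in minors) {
      rows <- genotype != "N"
      x <- as.numeric(genotype[rows] == al)
      designs[[length(designs) + 1L]] <-
        build_design(al, rows, x, covariates)
    }
  } else {
    rows <- !is.na(genotype)
    designs[[1L]] <- build_design("dosage", rows,
                                  as.numeric(genotype[rows]), covariates)
  }
  designs
}

build_design <- function(allele, rows, x, covariates) {
  if (length(unique(x)) < 2L)
    return(list(allele = allele, rows = rows, X = NULL, skipped = TRUE,
                reason = "constant predictor after missing-data removal"))
  X <- cbind(`(Intercept)` = 1, allele = x)
  if (!is.null(covariates)) {
    cc <- covariate_columns(covariates[rows, , drop = FALSE])
    if (!is.null(cc)) X <- cbind(X, cc)
  }
  list(allele = allele, rows = rows, X = X, skipped = FALSE, reason = NA)
}

# OLS of (possibly many) response columns on a fixed design; inference for
# the predictor in column 2.
fit_ols_multi <- function(X, Y) {
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stopf("too few samples (%d) for %d design columns", n, p)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  XtXinv <- solve(crossprod(X))
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(XtXinv[2L, 2L] * sigma2)
  tval <- beta[2L, ] / se
  pval <- 2 * stats::pt(-abs(tval), df)
  data.frame(n = n, effect = unname(beta[2L, ]), se = unname(se),
             t = unname(tval), df = df, p = unname(pval))
}

#' Single association fit
#'
#' Ordinary least squares of one expression vector on one design from
#' [encode_design()]; effect, standard error, t and two-sided p (residual
#' t distribution) are reported for the allele predictor.
#'
#' @param y Numeric expression vector (all samples; the design's row
#'   selection is applied internally).
#' @param design One element of an [encode_design()] result.
#' @return One-row data frame: `allele`, `n`, `effect`, `se`, `t`, `df`,
#'   `p`; `NULL` when the design was skipped.
#' @export
fit_linear <- function(y, design) {
  if (isTRUE(design$skipped)) return(NULL)
  fit <- fit_ols_multi(design$X, y[design$rows])
  cbind(data.frame(allele = design$allele, stringsAsFactors = FALSE), fit)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha Family-wise error rate in `(0, 1)`.
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (n_tests < 1) stopf("n_tests must be >= 1")
  alpha / n_tests
}

#' Association scan over all retained sites and genes
#'
#' Applies [site_filters()], encodes each site's design(s) and fits every
#' (site, tested allele, gene) pair by OLS with covariates.  Results are
#' sorted by p-value; the family's test count and Bonferroni threshold are
#' attached as attributes (`n_tests` always equals the number of emitted
#' results).
#'
#' @param expr Numeric matrix genes x samples (normalized expression),
#'   columns aligned with the genotype columns.
#' @param genotypes Sites x samples genotype matrix.
#' @param covariates Optional covariate data frame (one row per sample).
#' @param family Family label recorded on every result (e.g.
#'   `"mtDNA-scan"`, `"nuclear-scan"`).
#' @param min_carriers,max_major_freq Site filters (defaults 10 and 0.95).
#' @param alpha Family-wise error rate used for the attached Bonferroni
#'   threshold.
#' @return Data frame of association results with columns `site`,
#'   `allele`, `gene`, `n`, `effect`, `se`, `t`, `df`, `p`, `family`;
#'   attributes `n_tests`, `bonferroni`, `skipped` (data frame of skipped
#'   designs with reasons).
#' @export
eqtl_scan <- function(expr, genotypes, covariates = NULL,
                      family = "mtDNA-scan", min_carriers = 10L,
                      max_major_freq = 0.95, alpha = 0.05) {
  expr <- as.matrix(expr)
  if (ncol(expr) != ncol(genotypes))
    stopf("expression and genotype matrices are not sample-aligned")
  G <- site_filters(genotypes, min_carriers, max_major_freq)
  ploidy <- genotype_ploidy(G)
  res <- list()
  skipped <- list()
  for (i in seq_len(nrow(G))) {
    site <- rownames(G)[i] %||% as.character(i)
    designs <- encode_design(G[i, ], covariates, ploidy)
    for (d in designs) {
      if (isTRUE(d$skipped)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(site = site, allele = d$allele, reason = d$reason,
                     stringsAsFactors = FALSE)
        next
      }
      fit <- fit_ols_multi(d$X, t(expr[, d$rows, drop = FALSE]))
      res[[length(res) + 1L]] <- cbind(
        data.frame(site = site, allele = d$allele,
                   gene = rownames(expr) %||%
                     paste0("gene", seq_len(nrow(expr))),
                   stringsAsFactors = FALSE),
        fit)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(site = character(), allele = character(),
               gene = character(), n = integer(), effect = numeric(),
               se = numeric(), t = numeric(), df = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  out$family <- rep(family, nrow(out))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  attr(out, "bonferroni") <- if (nrow(out))
    bonferroni_threshold(alpha, nrow(out)) else NA_real_
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else NULL
  out
}

#' Per-population stratified scans
#'
#' Runs an independent [eqtl_scan()] within each stratum, with
#' stratum-specific site filters and Bonferroni family sizes.  Strata
#' smaller than `min_n` are skipped with a warning.
#'
#' @param expr,genotypes,covariates As in [eqtl_scan()].
#' @param strata Stratum label per sample (e.g. population).
#' @param min_n Minimum stratum size (default 30).
#' @param ... Passed to [eqtl_scan()].
#' @return Named list of per-stratum result data frames.
#' @export
stratified_scan <- function(expr, genotypes, covariates = NULL, strata,
                            min_n = 30L, ...) {
  expr <- as.matrix(expr)
  out <- list()
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < min_n) {
      warning(sprintf("stratum '%s' has %d < %d samples; skipped",
                      s, length(idx), min_n), call. = FALSE)
      next
    }
    g <- genotypes[, idx, drop = FALSE]
    attr(g, "ploidy") <- genotype_ploidy(genotypes)
    out[[s]] <- eqtl_scan(expr[, idx, drop = FALSE], g,
                          if (!is.null(covariates))
                            covariates[idx, , drop = FALSE],
                          family = paste0("stratified:", s), ...)
  }
  out
}

#' Background-masking contrast for one site and gene
#'
#' Quantifies how pooling samples from genetic backgrounds with differing
#' allele effects can mask an association: reports the pooled allele
#' effect, each background's own allele effect, and a heterogeneity test
#' between backgrounds (Wald z on the difference of effects for two
#' backgrounds; a Cochran-style Q against the inverse-variance pooled
#' effect for more).
#'
#' @param y Expression vector.
#' @param genotype Haploid allele vector for the site.
#' @param backgrounds Background label per sample (e.g. population).
#' @param covariates Optional covariate data frame.
#' @param allele Tested allele; defaults to the global minor allele.
#' @return List with `allele`, `pooled` (one-row fit), `per_background`
#'   (data frame), `heterogeneity` (list with `stat`, `df`, `p`, or `NULL`
#'   when fewer than two usable backgrounds) and `excluded` (backgrounds
#'   lacking both alleles).
#' @export
background_contrast <- function(y, genotype, backgrounds,
                                covariates = NULL, allele = NULL) {
  called <- genotype != "N"
  tab <- sort(table(genotype[called]), decreasing = TRUE)
  if (length(tab) < 2L) stopf("site is monomorphic")
  allele <- allele %||% names(tab)[2L]

  usable <- character(); excluded <- character()
  for (b in unique(backgrounds)) {
    g <- genotype[backgrounds == b]
    has_both <- any(g == allele) && any(g != allele & g != "N")
    if (has_both) usable <- c(usable, b) else excluded <- c(excluded, b)
  }
  if (length(usable) < 1L) stopf("no background carries both alleles")

  fit_subset <- function(idx) {
    g <- genotype[idx]
    rows <- g != "N"
    d <- build_design(allele, rows, as.numeric(g[rows] == allele),
                      if (!is.null(covariates))
                        covariates[idx, , drop = FALSE])
    if (isTRUE(d$skipped)) return(NULL)
    fit_linear(y[idx], d)
  }

  per_bg <- do.call(rbind, lapply(usable, function(b) {
    f <- fit_subset(which(backgrounds == b))
    if (is.null(f)) return(NULL)
    cbind(data.frame(background = b, stringsAsFactors = FALSE), f)
  }))
  pooled <- fit_subset(which(backgrounds %in% usable))

  het <- NULL
  if (!is.null(per_bg) && nrow(per_bg) >= 2L) {
    if (nrow(per_bg) == 2L) {
      z <- (per_bg$effect[1] - per_bg$effect[2]) /
        sqrt(per_bg$se[1]^2 + per_bg$se[2]^2)
      het <- list(stat = z, df = 1,
                  p = 2 * stats::pnorm(-abs(z)))
    } else {
      w <- 1 / per_bg$se^2
      mu <- sum(w * per_bg$effect) / sum(w)
      q <- sum(w * (per_bg$effect - mu)^2)
      het <- list(stat = q, df = nrow(per_bg) - 1L,
                  p = stats::pchisq(q, nrow(per_bg) - 1L,
                                    lower.tail = FALSE))
    }
  }
  list(allele = allele, pooled = pooled, per_background = per_bg,
       heterogeneity = het, excluded = excluded)
}
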