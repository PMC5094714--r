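## Co-expression screen and enrichment statistics.
##
## Stage 1 screens every (mtDNA gene, nuclear gene) pair by Pearson
## correlation, with a Bonferroni family equal to the full number of
## pairs.  Stage 2 keeps only screened nuclear genes that are also
## differentially expressed between the L and non-L macro-groups in the
## covariate-adjusted linear model, with a Bonferroni family equal to the
## number of stage-1 survivors.  Gene-set enrichment of the final list is
## summarized by observed/expected fold enrichment and an upper
## hypergeometric tail probability per annotation term.

#' Pearson co-expression screen
#'
#' Tests all (mtDNA gene, nuclear gene) pairs; the two-sided p-value uses
#' the exact t transform of r on `n - 2` degrees of freedom.  Pairs
#' involving a zero-variance expression vector are skipped and logged.
#' The Bonferroni family is the full pair count (#mt genes x #nuclear
#' genes), including skipped pairs.
#'
#' @param mt_expr Matrix of mtDNA gene expression, genes x samples.
#' @param nuc_expr Matrix of nuclear gene expression, genes x samples
#'   (same sample order).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame of retained pairs (`mt_gene`, `nuclear_gene`, `r`,
#'   `n`, `p`), sorted by p; attributes `family`, `threshold`, `skipped`.
#' @export
pearson_screen <- function(mt_expr, nuc_expr, alpha = 0.05) {
  mt_expr <- as.matrix(mt_expr); nuc_expr <- as.matrix(nuc_expr)
  if (is.null(rownames(mt_expr)))
    rownames(mt_expr) <- paste0("mt", seq_len(nrow(mt_expr)))
  if (is.null(rownames(nuc_expr)))
    rownames(nuc_expr) <- paste0("nuc", seq_len(nrow(nuc_expr)))
  n <- ncol(mt_expr)
  if (ncol(nuc_expr) != n)
    stopf("matrices are not sample-aligned")
  if (n < 4L) stopf("need at least 4 samples")
  family <- nrow(mt_expr) * nrow(nuc_expr)
  thr <- bonferroni_threshold(alpha, family)

  sd_mt <- apply(mt_expr, 1, stats::sd)
  sd_nuc <- apply(nuc_expr, 1, stats::sd)
  ok_mt <- sd_mt > 0; ok_nuc <- sd_nuc > 0
  skipped <- c(rownames(mt_expr)[!ok_mt], rownames(nuc_expr)[!ok_nuc])

  r <- stats::cor(t(mt_expr[ok_mt, , drop = FALSE]),
                  t(nuc_expr[ok_nuc, , drop = FALSE]))
  r_cl <- pmin(pmax(r, -1), 1)
  tstat <- r_cl * sqrt((n - 2) / pmax(1 - r_cl^2, .Machine$double.eps))
  tstat[abs(r_cl) == 1] <- Inf * sign(r_cl[abs(r_cl) == 1])
  p <- 2 * stats::pt(-abs(tstat), n - 2)

  hit <- which(p < thr, arr.ind = TRUE)
  out <- data.frame(
    mt_gene = rownames(r)[hit[, 1]],
    nuclear_gene = colnames(r)[hit[, 2]],
    r = r[hit], n = rep.int(n, nrow(hit)), p = p[hit],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "family") <- family
  attr(out, "threshold") <- thr
  attr(out, "skipped") <- skipped
  out
}

#' Two-stage differential filter
#'
#' Stage 2 of the co-expression screen: each candidate nuclear gene is fit
#' with the macro-group (L vs non-L) as predictor plus covariates, and
#' kept iff its p-value passes the Bonferroni threshold whose family size
#' defaults to the number of candidates (the stage-1 survivors).
#'
#' @param candidates A [pearson_screen()] result or a character vector of
#'   nuclear gene ids.
#' @param expression Normalized nuclear expression matrix, genes x
#'   samples.
#' @param groups Macro-group label per sample (`"L"` / `"nonL"`).
#' @param covariates Optional covariate data frame.
#' @param alpha2 Family-wise error rate for stage 2 (default 0.05).
#' @param family2 Stage-2 family size; defaults to the number of
#'   candidate genes.
#' @return Data frame with `gene`, `p_coexpr` (best stage-1 p per gene,
#'   `NA` when candidates were supplied as a plain vector) and `p_group`,
#'   restricted to genes passing both stages; attribute `threshold2`.
#' @export
two_stage_filter <- function(candidates, expression, groups,
                             covariates = NULL, alpha2 = 0.05,
                             family2 = NULL) {
  expression <- as.matrix(expression)
  if (is.data.frame(candidates)) {
    genes <- unique(candidates$nuclear_gene)
    p1 <- vapply(genes, function(g)
      min(candidates$p[candidates$nuclear_gene == g]), numeric(1))
  } else {
    genes <- unique(as.character(candidates))
    p1 <- rep(NA_real_, length(genes))
  }
  if (!length(genes))
    return(structure(data.frame(gene = character(), p_coexpr = numeric(),
                                p_group = numeric(),
                                stringsAsFactors = FALSE),
                     threshold2 = NA_real_))
  absent <- setdiff(genes, rownames(expression))
  if (length(absent))
    stopf("candidate gene(s) absent from the expression matrix: %s",
          paste(absent, collapse = ", "))
  family2 <- family2 %||% length(genes)
  thr2 <- bonferroni_threshold(alpha2, family2)

  x <- as.numeric(groups == "L")
  design <- build_design("L", rep(TRUE, length(x)), x, covariates)
  if (isTRUE(design$skipped)) stopf("macro-group labels do not vary")
  fit <- fit_ols_multi(design$X,
                       t(expression[genes, , drop = FALSE]))
  out <- data.frame(gene = genes, p_coexpr = unname(p1),
                    p_group = fit$p, stringsAsFactors = FALSE)
  out <- out[out$p_group < thr2, , drop = FALSE]
  out <- out[order(out$p_group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold2") <- thr2
  out
}

#' Direction of group differences for a gene list
#'
#' Per-gene ratio of mean normalized expression in the L macro-group over
#' the non-L mean, and the share of genes with ratio above 1.
#'
#' @param genes Character vector of gene ids.
#' @param norm_expr Normalized expression matrix, genes x samples.
#' @param groups Macro-group label per sample (`"L"` / `"nonL"`).
#' @return Data frame with `gene`, `ratio_L_over_nonL`, `direction`;
#'   attribute `share_up` (fraction with ratio > 1).
#' @export
direction_summary <- function(genes, norm_expr, groups) {
  norm_expr <- as.matrix(norm_expr)
  in_l <- groups == "L"
  if (!any(in_l) || all(in_l)) stopf("both groups must be non-empty")
  absent <- setdiff(genes, rownames(norm_expr))
  if (length(absent))
    stopf("gene(s) absent from the expression matrix: %s",
          paste(absent, collapse = ", "))
  m_l <- rowMeans(norm_expr[genes, in_l, drop = FALSE])
  m_n <- rowMeans(norm_expr[genes, !in_l, drop = FALSE])
  ratio <- m_l / m_n
  out <- data.frame(gene = genes, ratio_L_over_nonL = unname(ratio),
                    direction = ifelse(ratio > 1, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "share_up") <- mean(ratio > 1)
  out
}

#' Gene-set term enrichment
#'
#' For each annotation term: observed = genes of the set annotated with
#' the term, expected = set size x (term genes in background) /
#' (background size), fold = observed/expected, and p = upper
#' hypergeometric tail `P(X >= observed)`.  Terms with no background
#' genes are skipped.
#'
#' @param gene_set Character vector, must be a subset of `background`.
#' @param background Character vector of background gene ids.
#' @param annotation Data frame with columns `term` and `gene`.
#' @return Data frame with `term`, `observed`, `expected`, `fold`, `p`,
#'   sorted by p.
#' @export
enrichment_test <- function(gene_set, background, annotation) {
  background <- unique(background)
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, background)
  if (length(outside))
    stopf("gene set not contained in background (e.g. %s)", outside[1])
  if (!all(c("term", "gene") %in% names(annotation)))
    stopf("annotation needs columns term, gene")
  n_bg <- length(background)
  n_set <- length(gene_set)
  rows <- lapply(split(annotation$gene, annotation$term), unique)
  out <- do.call(rbind, lapply(names(rows), function(tm) {
    term_bg <- intersect(rows[[tm]], background)
    k <- length(term_bg)
    if (k == 0L) return(NULL)
    obs <- length(intersect(gene_set, term_bg))
    expd <- n_set * k / n_bg
    data.frame(term = tm, observed = obs, expected = expd,
               fold = obs / expd,
               p = stats::phyper(obs - 1, k, n_bg - k, n_set,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(term = character(), observed = integer(),
                      expected = numeric(), fold = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
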