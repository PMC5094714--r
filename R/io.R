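## Plain-text readers and writers for the pipeline's tabular interchange
## formats.  Pileups, count matrices, genotype matrices, covariates,
## defining-variant tables and coverage summaries travel as TSV; consensus
## sequences as FASTA; variant calls as a minimal VCF-like TSV
## (POS, REF, ALT, AF).

#' Read / write a base-count pileup TSV
#'
#' Columns: `position`, `A`, `C`, `G`, `T`.
#'
#' @param path File path.
#' @return `read_pileup_tsv`: integer matrix positions x 4 (rows ordered
#'   by position).
#' @export
read_pileup_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(d)))
    stopf("pileup TSV needs columns %s", paste(need, collapse = ", "))
  d <- d[order(d$position), , drop = FALSE]
  m <- as.matrix(d[, BASES])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

#' @rdname read_pileup_tsv
#' @param pileup Integer matrix positions x 4 with columns A, C, G, T.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(
    data.frame(position = seq_len(nrow(pileup)), pileup),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-by-sample count matrix TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param path File path.
#' @return `read_counts_tsv`: numeric matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_counts_tsv
#' @param counts Matrix with gene rownames.
#' @export
write_counts_tsv <- function(counts, path) {
  d <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write consensus sequences as FASTA
#'
#' @param seqs Named character vector/list of sequence strings.
#' @param path File path.
#' @param width Line width for sequence wrapping.
#' @export
write_consensus_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a FASTA file of consensus sequences
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_consensus_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stopf("no FASTA headers in %s", path)
  idx <- cumsum(hdr)
  names_ <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 paste, character(1), collapse = "")
  stats::setNames(unname(seqs), names_)
}

#' Write variant calls as a minimal VCF-like TSV (POS, REF, ALT, AF)
#'
#' @param variants Data frame from [call_variants()].
#' @param path File path.
#' @export
write_variants_tsv <- function(variants, path) {
  d <- data.frame(POS = variants$position, REF = variants$ref,
                  ALT = variants$alt, AF = variants$af)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a haplogroup defining-variant table TSV
#'
#' Columns: `clade`, `parent`, `position`, `derived_allele`.
#'
#' @param path File path.
#' @return `read_haplogroup_defs_tsv`: a [haplogroup_definition()].
#' @export
read_haplogroup_defs_tsv <- function(path) {
  haplogroup_definition(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_haplogroup_defs_tsv
#' @param defs A [haplogroup_definition()] or its underlying table.
#' @export
write_haplogroup_defs_tsv <- function(defs, path) {
  tab <- if (inherits(defs, "haplogroup_def")) defs$table else defs
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a genotype matrix TSV
#'
#' First column `site`, remaining columns one per sample; haploid allele
#' letters or diploid dosages.
#'
#' @param path File path.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return `read_genotypes_tsv`: sites x samples matrix with `ploidy`
#'   attribute.
#' @export
read_genotypes_tsv <- function(path, ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE,
                         colClasses = if (ploidy == "haploid") "character")
  m <- as.matrix(d[, -1, drop = FALSE])
  if (ploidy == "diploid") storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  attr(m, "ploidy") <- ploidy
  m
}

#' @rdname read_genotypes_tsv
#' @param genotypes Sites x samples matrix.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  d <- data.frame(site = rownames(genotypes), genotypes,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write association results as TSV
#'
#' @param results An [eqtl_scan()] result data frame.
#' @param path File path.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
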