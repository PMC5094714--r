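## Haplogroup assignment and phylogeny.
##
## Haplogroups are clades of mtDNA sequences sharing defining variants.
## Assignment scores each clade by the fraction of its cumulative
## root-to-clade defining variants observed in a sample's variant list;
## private extra variants are not penalized (singletons are expected).
## A neighbor-joining tree over per-site p-distances verifies that the
## reconstructed sequences separate the planted macro-haplogroups.

#' Haplogroup definition table
#'
#' Builds a rooted clade tree from a defining-variant table.  The root is
#' the unique label that appears as a parent but never as a clade; it
#' carries no defining variants.  A (position, allele) pair may recur on
#' several independent branches (homoplasy).
#'
#' @param defs Data frame with columns `clade`, `parent`, `position`,
#'   `derived_allele`; one row per defining variant.
#' @param ref_length If given, positions must lie in `[1, ref_length]`.
#' @param clades,parents Optional explicit clade list and named
#'   clade-to-parent map, needed when some clade carries no defining
#'   variants of its own.
#' @return An object of class `haplogroup_def` with elements `table`,
#'   `root`, `clades`, `parent` (named vector), `depth` (named integer
#'   vector, root = 0) and `path` (named list of cumulative defining
#'   variant data frames along the root-to-clade path).
#' @export
haplogroup_definition <- function(defs, ref_length = NULL, clades = NULL,
                                  parents = NULL) {
  need <- c("clade", "parent", "position", "derived_allele")
  if (!all(need %in% names(defs)))
    stopf("defs needs columns %s", paste(need, collapse = ", "))
  if (!is.null(ref_length) &&
      any(defs$position < 1 | defs$position > ref_length))
    stopf("defining variant position outside the reference length")
  if (!all(defs$derived_allele %in% BASES))
    stopf("derived alleles must be A, C, G or T")
  clades <- clades %||% unique(defs$clade)
  parent <- vapply(clades, function(cl) {
    p <- unique(c(defs$parent[defs$clade == cl], parents[cl]))
    p <- p[!is.na(p)]
    if (length(p) != 1L)
      stopf("clade '%s' needs exactly one parent, found %d", cl, length(p))
    p
  }, character(1))
  root <- setdiff(unique(parent), clades)
  if (length(root) != 1L)
    stopf("expected exactly one root label, found: %s",
          paste(root, collapse = ", "))

  depth <- c(stats::setNames(0L, root))
  path <- stats::setNames(vector("list", length(clades) + 1L),
                          c(root, clades))
  path[[root]] <- defs[0, c("position", "derived_allele")]
  resolve <- function(cl) {
    if (!is.null(path[[cl]])) return(invisible())
    p <- parent[[cl]]
    if (!p %in% names(path)) stopf("clade '%s' has unknown parent '%s'",
                                   cl, p)
    resolve(p)
    own <- defs[defs$clade == cl, c("position", "derived_allele")]
    path[[cl]] <<- rbind(path[[p]], own)
    depth[cl] <<- depth[[p]] + 1L
    invisible()
  }
  for (cl in clades) resolve(cl)

  structure(list(table = defs, root = root, clades = clades,
                 parent = parent, depth = depth, path = path),
            class = "haplogroup_def")
}

#' Assign a haplogroup from a variant list
#'
#' Each clade is scored as (number of its cumulative root-to-clade defining
#' variants matched by the sample's variant list) / (number of cumulative
#' defining variants on that path); private extra variants are not
#' penalized.  Among the clades with the maximal score, the one matching
#' the most path variants wins (so a fully matched subclade beats its
#' ancestors); remaining ties are broken toward the shallower clade and
#' then alphabetically.  The root, whose empty path scores 1 vacuously, is
#' returned only when no clade matches anything (e.g. an empty variant
#' list).
#'
#' @param variants Data frame of the sample's substitutions with columns
#'   `position` and `alt` (as from [call_variants()]; a `derived_allele`
#'   column is also accepted).
#' @param defs A [haplogroup_definition()].
#' @param missing_positions Positions called `N` in the sample; if every
#'   defining position of the tree is missing, the sample is flagged
#'   unassigned.
#' @return List with `clade`, `score` and `unassigned`.
#' @export
assign_haplogroup <- function(variants, defs, missing_positions = integer()) {
  stopifnot(inherits(defs, "haplogroup_def"))
  alt_col <- if ("alt" %in% names(variants)) "alt" else "derived_allele"
  all_def_pos <- unique(defs$table$position)
  if (length(missing_positions) &&
      all(all_def_pos %in% missing_positions))
    return(list(clade = NA_character_, score = NA_real_, unassigned = TRUE))

  have <- paste(variants$position, variants[[alt_col]])
  labels <- setdiff(names(defs$path), defs$root)
  matched <- vapply(labels, function(cl) {
    p <- defs$path[[cl]]
    sum(paste(p$position, p$derived_allele) %in% have)
  }, numeric(1))
  path_len <- vapply(labels, function(cl) nrow(defs$path[[cl]]),
                     numeric(1))
  score <- ifelse(path_len > 0, matched / path_len, 1)
  if (all(matched == 0))
    return(list(clade = defs$root, score = 1, unassigned = FALSE))
  cand <- labels[score == max(score)]
  cand <- cand[order(-matched[cand], defs$depth[cand], cand)]
  list(clade = cand[1L], score = max(score), unassigned = FALSE)
}

#' Pairwise p-distance matrix
#'
#' Per-site mismatch proportion between co-linear sequences with pairwise
#' deletion: positions where either sequence is `N` are excluded from both
#' numerator and denominator.
#'
#' @param seqs Named character vector or list of equal-length sequence
#'   strings over `{A,C,G,T,N}`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(seqs) {
  seqs <- unlist(seqs)
  n <- length(seqs)
  if (n < 2L) stopf("need at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stopf("sequences must have equal length")
  ids <- names(seqs) %||% paste0("seq", seq_len(n))
  chars <- do.call(rbind, lapply(seqs, split_bases))
  known <- chars != "N"
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- known[i, ] & known[j, ]
      nc <- sum(comp)
      if (nc == 0L) stopf("no comparable sites between %s and %s",
                          ids[i], ids[j])
      D[i, j] <- D[j, i] <- sum(chars[i, comp] != chars[j, comp]) / nc
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Classic neighbor joining (Saitou-Nei agglomeration by Q-matrix
#' minimization with the standard branch-length formulas).  On an additive
#' distance matrix the generating topology is recovered and path lengths
#' reproduce the input distances.  Ties in the Q matrix are broken toward
#' the lexicographically smallest pair of current node indices, making the
#' merge order deterministic.  A negative branch length is clamped to zero
#' with the residual moved to its sibling branch, preserving the distance
#' between the joined pair.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal and
#'   at least 3 taxa.
#' @return A newick string with branch lengths (6 decimal places).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stopf("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12)))
    stopf("distance matrix must be symmetric")
  if (any(D < 0)) stopf("distances must be non-negative")
  if (any(diag(D) != 0)) stopf("diagonal must be zero")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  node <- labels  # newick fragment per active node

  fmt <- function(x) sprintf("%.6f", x)
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (length(node) > 3L) {
    m <- length(node)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(1L, 2L)
    bq <- Q[1L, 2L]
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      if (Q[i, j] < bq - 1e-15) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    l <- clamp_pair(li, lj)
    newf <- sprintf("(%s:%s,%s:%s)", node[i], fmt(l[1]), node[j], fmt(l[2]))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    node <- c(node[keep], newf)
  }
  dAB <- D[1, 2]; dAC <- D[1, 3]; dBC <- D[2, 3]
  la <- max((dAB + dAC - dBC) / 2, 0)
  lb <- max((dAB + dBC - dAC) / 2, 0)
  lc <- max((dAC + dBC - dAB) / 2, 0)
  sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt(la), node[2], fmt(lb),
          node[3], fmt(lc))
}

#' Is a taxon subset monophyletic on an unrooted tree?
#'
#' True iff some edge bipartition of the tree separates exactly the given
#' subset from the remaining taxa.  The full taxon set and singletons are
#' trivially monophyletic.
#'
#' @param tree A newick string or an `ape` `phylo` object.
#' @param taxa Character vector of tip labels.
#' @return Logical scalar.
#' @export
check_monophyly <- function(tree, taxa) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!all(taxa %in% tree$tip.label))
    stopf("taxa not in tree: %s",
          paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  taxa <- sort(unique(taxa))
  all_tips <- sort(tree$tip.label)
  if (length(taxa) == length(all_tips) || length(taxa) == 1L) return(TRUE)
  parts <- ape::prop.part(tree)
  for (p in parts) {
    set <- sort(tree$tip.label[p])
    if (identical(set, taxa) ||
        identical(sort(setdiff(all_tips, set)), taxa)) return(TRUE)
  }
  FALSE
}
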