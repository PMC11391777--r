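# Alignment trimming, p-distances, neighbor-joining trees (with negative
# branch-length clean-up), leaf branch-length features and cophenetic
# distances. Trees are ape "phylo" objects throughout, so externally built
# newick trees drop in directly via ape::read.tree().

#' Build an alignment object from gapped sequences
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (gap character \code{"-"}).
#' @return Character matrix, one row per sequence, one column per alignment
#'   column, with sequence ids as rownames.
#' @export
as_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("alignment sequences need unique names", call. = FALSE)
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1) {
    stop("gapped sequences differ in length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Read an aligned FASTA file as an alignment matrix
#'
#' @param path Path to an aligned FASTA file.
#' @return Alignment character matrix (see [as_alignment()]).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  seqs <- as.character(set)
  names(seqs) <- ids
  as_alignment(seqs)
}

#' Remove gap-rich alignment columns
#'
#' A single gap-fraction rule approximating automated alignment trimming:
#' every column whose gap fraction exceeds \code{max_gap_fraction} is
#' dropped; row order is preserved. Idempotent at a fixed threshold.
#'
#' @param alignment Alignment matrix from [as_alignment()].
#' @param max_gap_fraction Columns with gap fraction strictly above this are
#'   removed; default 0.2.
#' @return The trimmed alignment matrix.
#' @export
trim_alignment <- function(alignment, max_gap_fraction = 0.2) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  gap_frac <- colMeans(alignment == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) {
    stop("trimming removed every alignment column", call. = FALSE)
  }
  alignment[, keep, drop = FALSE]
}

#' Pairwise p-distances from an alignment
#'
#' Entry (i, j) is the fraction of mismatching residues over the columns
#' where neither sequence has a gap (pairwise deletion).
#'
#' @param alignment Alignment matrix with >= 2 rows.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  n <- nrow(alignment)
  if (n < 2) stop("need >= 2 sequences", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(alignment),
                                       rownames(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- alignment[i, ] != "-" & alignment[j, ] != "-"
      if (!any(ok)) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     rownames(alignment)[i], rownames(alignment)[j]),
             call. = FALSE)
      }
      d[i, j] <- d[j, i] <-
        sum(alignment[i, ok] != alignment[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ via \code{ape::nj()}. Negative estimated branch lengths are
#' clamped to zero with the deficit moved onto the sibling branch, so every
#' branch length is non-negative while leaf-to-leaf path lengths are
#' preserved as closely as possible.
#'
#' @param d Square symmetric distance matrix with zero diagonal and row
#'   names as taxon labels; >= 3 taxa.
#' @return An ape \code{phylo} tree (unrooted).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need >= 3 taxa", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sib) > 0) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
      # a sibling pushed negative is picked up on the next sweep
      if (tree$edge.length[sib[1]] < 0) tree$edge.length[sib[1]] <- 0
    }
  }
  tree
}

#' Terminal branch length per leaf
#'
#' The phylogenetic feature column: length of the branch subtending each
#' leaf, keyed by leaf label.
#'
#' @param tree An ape \code{phylo} tree with branch lengths.
#' @return Named numeric vector, one entry per leaf.
#' @export
leaf_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  tip_edges <- match(seq_len(ntip), tree$edge[, 2])
  if (anyNA(tip_edges)) stop("leaf with missing branch", call. = FALSE)
  out <- tree$edge.length[tip_edges]
  if (anyNA(out)) stop("leaf with missing branch length", call. = FALSE)
  names(out) <- tree$tip.label
  out
}

#' Cophenetic (leaf-to-leaf path) distances
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j; the tree is treated as unrooted.
#'
#' @param tree An ape \code{phylo} tree with branch lengths and >= 2 leaves.
#' @return Symmetric numeric matrix over leaf labels with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  if (length(tree$tip.label) < 2) stop("need >= 2 leaves", call. = FALSE)
  stats::cophenetic(tree)
}
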