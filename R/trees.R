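# Distance-based trees for visualization and grouping checks.
#
# Tree inference itself is delegated to ape (neighbor joining, newick I/O,
# monophyly) and phangorn (midpoint rooting); this module supplies the
# p-distance plumbing, deterministic input validation, and a seeded
# column-resampling bootstrap.

#' Neighbor-joining tree from a distance matrix
#'
#' @param d Square symmetric distance matrix with zero diagonal (e.g. from
#'   [p_distance_matrix()]), a `dist`, or an [identity_matrix()] (converted
#'   to p-distance). At least 3 taxa required.
#' @return An `ape::phylo` tree. Negative branch-length estimates are
#'   clamped to 0 and flagged via the `clamped_edges` attribute.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "identity_matrix")) d <- 1 - unclass(d) / 100
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("d must be square")
  if (any(abs(d - t(d)) > 1e-8)) abort("d must be symmetric")
  if (any(diag(d) != 0)) abort("d must have a zero diagonal")
  if (nrow(d) < 3L) abort("neighbor joining requires >= 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  if (length(neg) > 0) tr$edge.length[neg] <- 0
  attr(tr, "clamped_edges") <- length(neg)
  tr
}

#' Midpoint-root a tree
#'
#' Roots at the midpoint of the longest leaf-to-leaf path. A tree of total
#' length 0 is rooted arbitrarily and flagged with a warning.
#'
#' @param tree An unrooted `phylo` with branch lengths.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (sum(tree$edge.length) == 0) {
    warn("zero-length tree: midpoint undefined, rooting arbitrarily")
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Test whether a set of leaves is monophyletic
#'
#' @param tree A `phylo`.
#' @param leaves Character vector of tip labels.
#' @return `TRUE` iff some edge bipartition separates exactly that set.
#' @export
is_monophyletic <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("unknown leaf label(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(leaves) <= 1L || length(leaves) == length(tree$tip.label)) {
    return(TRUE)
  }
  # a clade on either rooting side counts as a bipartition
  ape::is.monophyletic(tree, leaves) ||
    ape::is.monophyletic(tree, setdiff(tree$tip.label, leaves))
}

#' Neighbor-joining bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' p-distances for each replicate, and reports for each internal edge of
#' the original tree the fraction of replicates containing that
#' bipartition.
#'
#' @param aln Aligned sequence table (>= 3 rows, >= 2 columns).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed; the same seed yields identical supports.
#' @param gap_policy See [pairwise_identity()].
#' @return The original NJ `phylo` with `node.label` set to support
#'   fractions in `[0, 1]` (`NA` at the root).
#' @export
bootstrap_support <- function(aln, n_reps = 200, seed = 1,
                              gap_policy = "pairwise_deletion") {
  check_seq_tbl(aln)
  stopifnot(n_reps >= 1)
  if (!is_aligned(aln)) abort("sequences must be aligned")
  W <- nchar(aln$seq[1])
  if (W < 2) abort("alignment must have at least 2 columns")
  if (nrow(aln) < 3L) abort("bootstrap requires >= 3 sequences")
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(mat) <- aln$id
  base_tree <- nj_tree(p_distance_matrix(aln, gap_policy))
  tree_from <- function(m) {
    sub <- aln
    sub$seq <- apply(m, 1, paste, collapse = "")
    nj_tree(p_distance_matrix(sub, gap_policy))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(i) {
    tree_from(mat[, sample.int(W, W, replace = TRUE), drop = FALSE])
  })
  counts <- ape::prop.clades(base_tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  base_tree$node.label <- counts / n_reps
  base_tree
}

#' Read and write trees in newick format
#'
#' Thin wrappers over `ape::read.tree()` / `ape::write.tree()` so trees
#' round-trip with internal-node support labels.
#'
#' @param tree A `phylo`.
#' @param path File path.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
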