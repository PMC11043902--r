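#' Build a neighbour-joining functional tree from a distance matrix
#'
#' Standard Saitou-Nei neighbour joining (via [ape::nj()]) on a
#' functional distance matrix. Negative branch-length estimates, which
#' NJ can produce on non-additive input, are clamped to zero; the total
#' clamped mass is recorded in the `clamped` attribute and reported via
#' a message. Two taxa are special-cased as a single split of total
#' length d. The trifurcating node that ape stores as the root of the
#' unrooted NJ tree is retained as the reference root for rooted branch
#' operations.
#'
#' @param d a `dist_matrix` (or symmetric labelled matrix) of
#'   functional distances.
#' @return an [ape::phylo] tree whose tips are the species labels.
#' @export
nj_build <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs labels")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  if (any(d < 0)) stop("negative distances")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  if (n == 2) {
    tree <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2),
                           edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
                           tip.label = rownames(d), Nnode = 1L),
                      class = "phylo")
    attr(tree, "order") <- "cladewise"
    attr(tree, "clamped") <- 0
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  clamped <- -sum(tree$edge.length[neg])
  if (clamped > 0) {
    message(sprintf("nj_build: clamped %d negative branch length(s), total %.3g",
                    sum(neg), clamped))
    tree$edge.length[neg] <- 0
  }
  attr(tree, "clamped") <- clamped
  tree
}

# Logical edge x tip matrix: entry [e, t] is TRUE when tip t lies below
# edge e (on the far side from the stored root). One postorder pass.
edge_leaf_map <- function(tree) {
  nt <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  nnode <- nt + tree$Nnode
  below <- matrix(FALSE, nnode, nt)
  below[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  # rows aligned with tree$edge (original order)
  m <- below[tree$edge[, 2], , drop = FALSE]
  colnames(m) <- tree$tip.label
  m
}

#' Branches induced by a leaf subset
#'
#' Returns the edges of the minimal spanning (Steiner) subtree of the
#' functional tree connecting a set of leaves: an edge belongs to the
#' subtree when removing it separates members of the subset. A
#' singleton subset induces no edges.
#'
#' @param tree an [ape::phylo] tree.
#' @param leaves character vector of tip labels (non-empty subset).
#' @param map optional precomputed [edge_leaf_map] for `tree` (an
#'   internal cache used by per-region loops).
#' @return data.frame with columns `edge` (row index into `tree$edge`)
#'   and `length`.
#' @export
induced_branches <- function(tree, leaves, map = NULL) {
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown)) stop("unknown leaf label(s): ",
                            paste(unknown, collapse = ", "))
  if (!length(leaves)) stop("empty leaf subset")
  if (is.null(map)) map <- edge_leaf_map(tree)
  inside <- rowSums(map[, tree$tip.label %in% leaves, drop = FALSE])
  keep <- inside > 0 & inside < length(unique(leaves))
  data.frame(edge = which(keep), length = tree$edge.length[keep])
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path between two tips: the
#' edges whose removal separates exactly one of the two.
#'
#' @param tree an [ape::phylo] tree.
#' @param a,b tip labels.
#' @return numeric path length.
#' @export
patristic <- function(tree, a, b) {
  if (!all(c(a, b) %in% tree$tip.label))
    stop("unknown leaf label(s): ",
         paste(setdiff(c(a, b), tree$tip.label), collapse = ", "))
  if (a == b) return(0)
  map <- edge_leaf_map(tree)
  onpath <- xor(map[, a], map[, b])
  sum(tree$edge.length[onpath])
}

#' Total branch length of a tree
#' @param tree an [ape::phylo] tree.
#' @return numeric sum of all edge lengths.
#' @export
total_branch_length <- function(tree) sum(tree$edge.length)

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()] fixing
#' the on-disk convention: plain Newick with branch lengths.
#'
#' @param path file path.
#' @return `read_newick` returns an [ape::phylo]; `write_newick`
#'   returns `path` invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
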