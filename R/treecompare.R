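#' Restrict two trees to their shared leaves
#'
#' Reference trees typically cover a different species set than the
#' recovered tree, so both are pruned to the intersection of their leaf
#' sets before comparison. Degree-2 nodes created by pruning are
#' contracted with branch lengths merged additively (via
#' [ape::keep.tip()]).
#'
#' @param source,ref [ape::phylo] trees.
#' @return A list with pruned `source` and `ref` trees.
#' @export
prune_to_shared <- function(source, ref) {
  stopifnot(inherits(source, "phylo"), inherits(ref, "phylo"))
  shared <- intersect(source$tip.label, ref$tip.label)
  if (length(shared) < 4L) {
    abort(sprintf(
      "Only %d shared leaves; at least 4 are needed for an unrooted comparison.",
      length(shared)), class = "camphy_insufficient_overlap")
  }
  list(
    source = ape::keep.tip(source, shared),
    ref = ape::keep.tip(ref, shared)
  )
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves in two; the
#' split is non-trivial when both sides hold at least 2 leaves.
#' Polytomies simply contribute fewer bipartitions. Splits are
#' canonicalized as the sorted, comma-joined side containing the
#' lexicographically smallest leaf label, so they compare across trees
#' regardless of rooting or child order.
#'
#' @param tree An [ape::phylo] tree with at least 4 leaves.
#' @return Character vector of canonical split keys (possibly empty,
#'   e.g. for a star tree).
#' @examples
#' tree_bipartitions(read_newick("((A,B),(C,D));"))
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  n_tip <- length(labels)
  if (n_tip < 4L) {
    abort("Bipartitions need a tree with at least 4 leaves.",
          class = "camphy_usage")
  }
  anchor <- min(labels)
  # leaf set under each node, built in postorder
  tree <- stats::reorder(tree, "postorder")
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- labels[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n_tip) next                     # pendant edge: trivial
    side <- below[[ch]]
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    if (!anchor %in% side) side <- setdiff(labels, side)
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  sort(unique(keys))
}

#' Edge similarity between two trees
#'
#' The percentage of the source tree's non-trivial bipartitions that are
#' also present in the reference tree, after pruning both trees to their
#' shared leaves. The comparison is unrooted, ignores branch lengths,
#' and tolerates polytomies; multifurcation splits are matched by exact
#' set identity. A fully unresolved source tree (no non-trivial splits)
#' scores 100 by convention, with a warning.
#'
#' @inheritParams prune_to_shared
#' @param denominator Which tree's split count normalizes the
#'   percentage: the `"source"` tree under evaluation (default) or the
#'   `"ref"` tree.
#' @return Percentage in `[0, 100]`.
#' @examples
#' t1 <- read_newick("((A,B),(C,D));")
#' edge_similarity(t1, t1)
#' @export
edge_similarity <- function(source, ref, denominator = c("source", "ref")) {
  denominator <- match.arg(denominator)
  pruned <- prune_to_shared(source, ref)
  bs <- tree_bipartitions(pruned$source)
  br <- tree_bipartitions(pruned$ref)
  denom <- if (denominator == "source") bs else br
  if (length(denom) == 0L) {
    warn("Tree has no non-trivial splits; similarity is 100 by convention.")
    return(100)
  }
  100 * length(intersect(bs, br)) / length(denom)
}
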