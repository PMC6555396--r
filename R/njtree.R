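#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor-joining with the Studier-Keppler O(n^3)
#' update. At each step the pair (i, j) minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`
#' is joined; limb lengths follow the standard formulas and the last
#' three clusters are joined into a single trifurcating anchor node, so
#' the result is an unrooted tree. Ties in Q are broken by the
#' lexicographically smallest pair of cluster representatives (the
#' smallest leaf label in each cluster) so the output is byte-identical
#' across platforms. Negative limb lengths are kept internally (they
#' preserve additivity) and only clamped to zero when serialized by
#' [write_newick()].
#'
#' @param m Labelled symmetric distance matrix (e.g. a `cam_dist`),
#'   3 or more taxa, finite entries.
#' @return An [ape::phylo] tree whose leaf labels equal the matrix
#'   labels.
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(m)
#' @export
nj_tree <- function(m) {
  m <- unclass(m)
  labels <- rownames(m)
  n <- length(labels)
  if (is.null(labels) || n < 3L) {
    abort("Neighbor-joining needs a labelled matrix with at least 3 taxa.",
          class = "camphy_usage")
  }
  if (!all(is.finite(m))) {
    abort("Distance matrix contains non-finite entries.",
          class = "camphy_invalid_matrix")
  }
  # clusters: newick fragment + representative (smallest leaf label);
  # fragments use safe placeholder labels, restored after parsing
  safe <- sprintf("t%06d", seq_len(n))
  frag <- safe
  rep_lab <- labels
  D <- m
  join_frag <- function(i, j, li, lj) {
    a <- sprintf("%s:%.15g", frag[i], li)
    b <- sprintf("%s:%.15g", frag[j], lj)
    if (rep_lab[j] < rep_lab[i]) { tmp <- a; a <- b; b <- tmp }
    paste0("(", a, ",", b, ")")
  }
  while (length(rep_lab) > 3L) {
    k <- length(rep_lab)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    key2 <- pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    new_frag <- join_frag(i, j, li, lj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  # final trifurcation: three-point limb lengths
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ord <- order(rep_lab)
  lens <- c(l1, l2, l3)[ord]
  parts <- sprintf("%s:%.15g", frag[ord], lens)
  txt <- paste0("(", paste(parts, collapse = ","), ");")
  tree <- ape::read.tree(text = txt)
  tree$tip.label <- labels[match(tree$tip.label, safe)]
  if (any(tree$edge.length < 0)) {
    inform(sprintf(
      "%d negative limb length(s); they will be clamped to 0 on output.",
      sum(tree$edge.length < 0)))
  }
  tree
}
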