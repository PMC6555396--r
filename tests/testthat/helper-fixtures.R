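# Shared fixtures: everything is built in code, no data files.

# A CDS that uses every codon except `averted`, each exactly once,
# in deterministic (sorted) order.
seq_averting <- function(averted) {
  paste(setdiff(cam_codons(), averted), collapse = "")
}

# Write a FASTA file of named sequences; returns the path.
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta"),
                        headers = NULL, gz = FALSE) {
  headers <- headers %||% paste0(">", names(seqs))
  lines <- as.vector(rbind(headers, unname(seqs)))
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A species profile with prescribed motif sets (list of codon vectors),
# built through the real pipeline: one realizing gene per motif.
profile_from_motifs <- function(species, motif_sets) {
  genes <- tibble::tibble(
    species = species,
    sequence = vapply(motif_sets, seq_averting, character(1))
  )
  build_species_profile(genes, mode = "codon", species = species)
}

# A profile with opaque motif keys, for set-arithmetic-only tests.
fake_profile <- function(species, keys, counts = NULL) {
  counts <- counts %||% stats::setNames(rep(1L, length(keys)), keys)
  camphy:::new_cam_profile(species, counts, sum(counts), "codon")
}

# Random unrooted binary tree with positive branch lengths.
random_binary_tree <- function(n_leaves, min_len = 0.1, max_len = 1) {
  tree <- ape::rtree(n_leaves, rooted = FALSE,
                     tip.label = sprintf("t%02d", seq_len(n_leaves)))
  tree$edge.length <- stats::runif(nrow(tree$edge), min_len, max_len)
  tree
}

# Path-length (additive) distance matrix of a tree, labels sorted.
tree_distances <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}

# Same unrooted topology?
same_topology <- function(a, b) {
  setequal(tree_bipartitions(a), tree_bipartitions(b)) &&
    setequal(a$tip.label, b$tip.label)
}

# Balanced 16-leaf tree, every branch one unit long: the fixed study
# tree for pipeline-recovery checks.
balanced_16_tree <- function() {
  cherry <- function(a, b) sprintf("(%s:1,%s:1):1", a, b)
  tips <- sprintf("s%02d", 1:16)
  lvl1 <- mapply(cherry, tips[c(TRUE, FALSE)], tips[c(FALSE, TRUE)])
  pair <- function(a, b) sprintf("(%s,%s):1", a, b)
  lvl2 <- mapply(pair, lvl1[c(TRUE, FALSE)], lvl1[c(FALSE, TRUE)])
  lvl3 <- mapply(pair, lvl2[c(TRUE, FALSE)], lvl2[c(FALSE, TRUE)])
  read_newick(sprintf("(%s,%s);", lvl3[1], lvl3[2]))
}
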