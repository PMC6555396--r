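newick_meta <- "[](){}:;,'\"\t\n "

quote_newick_label <- function(label) {
  if (grepl("[][(){}:;,'\"[:space:]]", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that accepts a file path or a
#' Newick string, allows polytomies and missing branch lengths (stored
#' as `NA`, never zero), and turns malformed input or duplicate leaf
#' labels into informative errors.
#'
#' @param x File path or a single Newick string.
#' @return An [ape::phylo] tree.
#' @examples
#' read_newick("(A,B,(C,D));")
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  text <- if (file.exists(x) && !grepl(";", x)) {
    paste(readLines(x), collapse = "")
  } else {
    x
  }
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close) {
    abort(sprintf(
      "Unbalanced parentheses in Newick input (%d open, %d close).",
      open, close), class = "camphy_parse_error")
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort("Could not parse Newick input.", class = "camphy_parse_error")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    abort(paste0("Duplicate leaf labels: ", paste(dup, collapse = ", ")),
          class = "camphy_parse_error")
  }
  tree
}

#' Write a tree as Newick text
#'
#' Serializes an [ape::phylo] tree with branch lengths to 6 decimal
#' places, quoting labels only when they contain Newick metacharacters.
#' Negative branch lengths (which canonical neighbor-joining can
#' produce) are clamped to zero on output, with a note; branch lengths
#' that are absent are omitted. The string is terminated by `";"`.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional output file path; when `NULL` the Newick string
#'   is returned.
#' @param digits Decimal places for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @examples
#' write_newick(read_newick("(A:1,(B:1,C:1):0.5);"))
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  lens <- if (has_len) tree$edge.length else rep(NA_real_, nrow(tree$edge))
  n_neg <- sum(lens < 0, na.rm = TRUE)
  if (n_neg > 0L) {
    inform(sprintf("Clamped %d negative branch length(s) to 0.", n_neg))
    lens[!is.na(lens) & lens < 0] <- 0
  }
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- paste0("%.", digits, "f")
  render <- function(node) {
    if (node <= n_tip) return(quote_newick_label(tree$tip.label[node]))
    kid_edges <- children[[as.character(node)]]
    parts <- vapply(kid_edges, function(e) {
      sub <- render(tree$edge[e, 2])
      if (is.na(lens[e])) sub else paste0(sub, ":", sprintf(fmt, lens[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- n_tip + 1L
  txt <- paste0(render(root), ";")
  if (is.null(path)) {
    txt
  } else {
    writeLines(txt, path)
    invisible(txt)
  }
}
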