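#' Codon and amino-acid alphabets
#'
#' The codon universe is the full 64-codon table, stop codons included:
#' a gene that never uses a stop codon genuinely averts it, and motifs in
#' which only stop codons are missing are valid (if extreme) motifs.
#'
#' @return Character vectors: the 64 codons (sorted), the 3 stop codons,
#'   the start codon, or the 20 standard amino-acid letters.
#' @examples
#' length(cam_codons())
#' cam_stop_codons()
#' @export
cam_codons <- function() {
  sort(as.vector(outer(
    outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
    c("A", "C", "G", "T"), paste0
  )))
}

#' @rdname cam_codons
#' @export
cam_stop_codons <- function() c("TAA", "TAG", "TGA")

#' @rdname cam_codons
#' @export
cam_start_codon <- function() "ATG"

#' @rdname cam_codons
#' @export
cam_amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Degrees of freedom of the motif space
#'
#' A typical gene uses the one start codon and exactly one of the three
#' stop codons, so only 64 - 1 - 2 = 61 codons are free to be used or
#' averted; the codon motif space therefore has 2^61 possible motifs.
#' Amino-acid motifs vary over the full 20-letter alphabet (2^20 motifs).
#'
#' @param mode `"codon"` or `"amino_acid"`.
#' @return Integer: 61 in codon mode, 20 in amino-acid mode.
#' @examples
#' motif_degrees_of_freedom("codon")
#' @export
motif_degrees_of_freedom <- function(mode = c("codon", "amino_acid")) {
  mode <- match.arg(mode)
  if (mode == "codon") {
    n_stops_unused <- length(cam_stop_codons()) - 1L
    length(cam_codons()) - length(cam_start_codon()) - n_stops_unused
  } else {
    length(cam_amino_acids())
  }
}
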