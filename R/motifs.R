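#' Normalize a raw coding sequence
#'
#' Uppercases, maps RNA `U` to `T`, and strips whitespace. Other
#' characters (IUPAC ambiguity codes and anything else) pass through
#' untouched; downstream codon handling decides what to do with them.
#'
#' @param raw Character vector of raw sequences.
#' @param id Optional record name(s) used in error messages.
#' @return Character vector of normalized DNA sequences.
#' @examples
#' normalize_sequence("augaaa")
#' @export
normalize_sequence <- function(raw, id = NULL) {
  if (length(raw) == 0L || any(!nzchar(raw))) {
    bad <- if (is.null(id)) "input" else paste(id[!nzchar(raw)], collapse = ", ")
    abort(paste0("Empty sequence for record: ", bad), class = "camphy_empty_sequence")
  }
  out <- toupper(gsub("[[:space:]]+", "", raw))
  gsub("U", "T", out, fixed = TRUE)
}

# in-frame, non-overlapping codons; trailing incomplete codon dropped
split_codons <- function(sequence, warn_trailing = TRUE) {
  n <- nchar(sequence)
  if (n %% 3L != 0L && warn_trailing) {
    warn(sprintf("Trailing incomplete codon (%d nt) dropped.", n %% 3L),
         class = "camphy_trailing_codon")
  }
  n_codon <- n %/% 3L
  if (n_codon == 0L) return(character(0))
  substring(sequence, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
}

#' Extract the codon aversion motif of one gene
#'
#' The motif is the set of all 64 codons (stop codons included) not
#' observed among the in-frame, non-overlapping codons of the sequence,
#' returned as a sorted character vector. A trailing incomplete codon is
#' dropped with a warning; codons containing any character outside
#' `{A,C,G,T}` (ambiguity codes) mark no table entry as used, since they
#' carry no evidence for any specific codon.
#'
#' @param sequence A single normalized DNA sequence (see
#'   [normalize_sequence()]) of length at least 3.
#' @return Sorted character vector of averted codons (possibly empty).
#' @examples
#' extract_codon_motif("ATGAAATAA")   # 61 codons averted
#' @export
extract_codon_motif <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 3L) {
    abort("Sequence shorter than one codon (3 nt) after normalization.",
          class = "camphy_too_short")
  }
  codons <- split_codons(sequence)
  used <- unique(codons[grepl("^[ACGT]{3}$", codons)])
  setdiff(cam_codons(), used)
}

#' Translate a coding sequence
#'
#' In-frame translation under a standard genetic-code table
#' (`Biostrings::getGeneticCode()` identifiers; default `"1"`, the
#' standard code). Stop codons emit `"*"`; any codon containing a
#' character outside `{A,C,G,T}` emits `"X"`. Translation does not halt
#' at internal stops. A trailing incomplete codon is dropped with a
#' warning.
#'
#' @inheritParams extract_codon_motif
#' @param genetic_code Genetic-code table identifier, passed to
#'   [Biostrings::getGeneticCode()].
#' @return Single amino-acid string.
#' @examples
#' translate_cds("ATGAAA")      # "MK"
#' translate_cds("ATGNNNAAA")   # "MXK"
#' @export
translate_cds <- function(sequence, genetic_code = "1") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 3L) {
    abort("Sequence shorter than one codon (3 nt) after normalization.",
          class = "camphy_too_short")
  }
  code <- tryCatch(
    Biostrings::getGeneticCode(as.character(genetic_code)),
    error = function(e) abort(
      paste0("Unknown genetic-code table: ", genetic_code),
      class = "camphy_bad_genetic_code")
  )
  codons <- split_codons(sequence)
  aa <- unname(code[codons])
  aa[is.na(aa) | !grepl("^[ACGT]{3}$", codons)] <- "X"
  paste(aa, collapse = "")
}

#' Extract the amino-acid aversion motif of one protein
#'
#' The sorted set of the 20 standard amino acids not observed in the
#' protein. Stop symbols (`*`) and ambiguous residues (`X`) are ignored:
#' they are neither alphabet members nor usage marks.
#'
#' @param protein A single amino-acid string (may contain `*` and `X`).
#' @return Sorted character vector of averted amino acids.
#' @examples
#' extract_aa_motif("MK*X")   # 18 amino acids other than M, K
#' @export
extract_aa_motif <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  used <- unique(strsplit(protein, "", fixed = TRUE)[[1]])
  setdiff(cam_amino_acids(), used)
}

# motif <-> key serialization: sorted codons joined by commas; the empty
# motif is the empty string. parse(serialize(x)) is the identity.
motif_key <- function(motif) paste(sort(motif), collapse = ",")

parse_motif <- function(key) {
  if (!nzchar(key)) return(character(0))
  strsplit(key, ",", fixed = TRUE)[[1]]
}

motif_size <- function(key) {
  n_comma <- vapply(gregexpr(",", key, fixed = TRUE),
                    function(m) if (m[1] == -1L) 0L else length(m), integer(1))
  ifelse(nzchar(key), n_comma + 1L, 0L)
}
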