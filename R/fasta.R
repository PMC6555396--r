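species_label_from_path <- function(path) {
  stem <- basename(path)
  stem <- sub("\\.gz$", "", stem, ignore.case = TRUE)
  sub("\\.(fasta|fa|fna|ffn)$", "", stem, ignore.case = TRUE)
}

#' Read coding sequences from a FASTA file
#'
#' Reads a (possibly gzip-compressed) CDS FASTA file into a tibble of
#' gene records, one row per sequence. Header-derived columns follow
#' RefSeq CDS FASTA conventions: `gene_id` is the value of a bracketed
#' `gene=` attribute (records without one keep `NA` and are never
#' collapsed by [select_longest_isoforms()]); `has_exception` is set when
#' the header contains any of `exception_markers`; `is_partial` when it
#' contains any of `partial_markers`. Sequences are normalized with
#' [normalize_sequence()].
#'
#' @param path Path to a FASTA or FASTA.gz file.
#' @param species Species label; defaults to the file stem (minus
#'   `.fasta`/`.fa`/`.fna`/`.ffn` and `.gz` suffixes).
#' @param gene_pattern Regular expression with one capture group that
#'   extracts the gene identifier from the header.
#' @param exception_markers,partial_markers Substrings (fixed,
#'   case-insensitive) that flag annotated exceptions / partial genes.
#' @return A tibble with columns `species`, `gene_id`, `header`,
#'   `sequence`, `length`, `is_partial`, `has_exception`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 [gene=abc]", "ATGAAATAA"), fa)
#' read_cds(fa, species = "demo")
#' @export
read_cds <- function(path,
                     species = NULL,
                     gene_pattern = "\\[gene=([^]]+)\\]",
                     exception_markers = c("exception", "transl_except"),
                     partial_markers = "partial") {
  if (!file.exists(path)) {
    abort(paste0("Cannot read FASTA file: ", path), class = "camphy_io_error")
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    abort(paste0("No sequences in FASTA file: ", path),
          class = "camphy_empty_species")
  }
  headers <- names(seqs)
  raw <- as.character(seqs)
  gene_id <- rep(NA_character_, length(headers))
  hit <- regexpr(gene_pattern, headers, perl = TRUE)
  has_gene <- hit != -1L
  if (any(has_gene)) {
    gene_id[has_gene] <- sub(paste0(".*", gene_pattern, ".*"), "\\1",
                             headers[has_gene], perl = TRUE)
  }
  marker_hit <- function(markers) {
    Reduce(`|`, lapply(markers, function(m) {
      grepl(m, headers, ignore.case = TRUE, fixed = FALSE)
    }), init = rep(FALSE, length(headers)))
  }
  tibble(
    species = species %||% species_label_from_path(path),
    gene_id = gene_id,
    header = headers,
    sequence = normalize_sequence(unname(raw), id = headers),
    length = nchar(normalize_sequence(unname(raw), id = headers)),
    is_partial = marker_hit(partial_markers),
    has_exception = marker_hit(exception_markers)
  )
}

#' Keep the longest isoform of each gene
#'
#' For each `gene_id`, retains only the longest sequence so that a gene
#' contributes the most codons it can use; ties are broken by first
#' appearance in file order. Records with `NA` gene identifiers are
#' always retained.
#'
#' @param genes Tibble of gene records, as from [read_cds()].
#' @return Filtered tibble, original row order preserved.
#' @export
select_longest_isoforms <- function(genes) {
  genes <- mutate(genes, .row = dplyr::row_number())
  tagged <- filter(genes, !is.na(.data$gene_id))
  keep <- tagged |>
    group_by(.data$species, .data$gene_id) |>
    slice(which.max(.data$length)) |>
    ungroup() |>
    pull(.data$.row)
  genes |>
    filter(is.na(.data$gene_id) | .data$.row %in% keep) |>
    arrange(.data$.row) |>
    dplyr::select(-".row")
}

#' Filter flagged gene records
#'
#' Drops records flagged as annotated exceptions and, optionally,
#' partial genes. Defaults match the main analysis: exceptions removed,
#' partial genes kept.
#'
#' @param genes Tibble of gene records.
#' @param drop_exceptions,drop_partials Logical flags.
#' @param quiet Suppress the per-filter messages.
#' @return Filtered tibble.
#' @export
filter_records <- function(genes, drop_exceptions = TRUE,
                           drop_partials = FALSE, quiet = FALSE) {
  labels <- unique(genes$species)
  if (drop_exceptions) {
    n_drop <- sum(genes$has_exception)
    if (n_drop > 0L && !quiet) {
      inform(sprintf("Removed %d record(s) with annotated exceptions.", n_drop))
    }
    genes <- filter(genes, !.data$has_exception)
  }
  if (drop_partials) {
    n_drop <- sum(genes$is_partial)
    if (n_drop > 0L && !quiet) {
      inform(sprintf("Removed %d partial record(s).", n_drop))
    }
    genes <- filter(genes, !.data$is_partial)
  }
  if (nrow(genes) == 0L) {
    abort(paste0("All records removed for species: ",
                 paste(labels, collapse = ", ")),
          class = "camphy_empty_species")
  }
  genes
}
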