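#' Per-gene aversion motifs as a tibble
#'
#' Computes the aversion motif of every gene record: in codon mode the
#' set of unused codons, in amino-acid mode the set of unused amino
#' acids after translation. Motifs are serialized as comma-joined sorted
#' strings (the empty motif is `""`), the internal currency of the whole
#' package.
#'
#' @param genes Tibble of gene records (see [read_cds()]).
#' @param mode `"codon"` or `"amino_acid"`.
#' @param genetic_code Genetic-code table for amino-acid mode.
#' @return `genes` with added columns `motif` and `motif_size`.
#' @export
gene_motifs <- function(genes, mode = c("codon", "amino_acid"),
                        genetic_code = "1") {
  mode <- match.arg(mode)
  extract_one <- if (mode == "codon") {
    function(s) extract_codon_motif(s)
  } else {
    function(s) extract_aa_motif(translate_cds(s, genetic_code))
  }
  keys <- vapply(genes$sequence, function(s) motif_key(extract_one(s)),
                 character(1), USE.NAMES = FALSE)
  mutate(genes, motif = keys, motif_size = motif_size(keys))
}

new_cam_profile <- function(species, counts, n_genes, mode) {
  counts <- counts[order(names(counts))]
  structure(
    list(species = species, motifs = names(counts),
         counts = counts, n_genes = n_genes, mode = mode),
    class = "cam_profile"
  )
}

#' Build the motif profile of one species
#'
#' Collects the unique aversion motifs across all genes of a species,
#' keeping per-motif occurrence counts and the contributing gene count.
#' Every gene contributes with equal weight regardless of annotation.
#' Four genes with motifs (AAA,ATA), (AAA,ACG,CTC), (AAA,ATA), (CGC)
#' yield the unique set \{(AAA,ATA), (AAA,ACG,CTC), (CGC)\} with the
#' first motif counted twice.
#'
#' @inheritParams gene_motifs
#' @param species Species label; defaults to the (single) label in
#'   `genes`.
#' @return A `cam_profile` object: species label, sorted unique motif
#'   keys, occurrence counts, gene count, and mode.
#' @export
build_species_profile <- function(genes, mode = c("codon", "amino_acid"),
                                  species = NULL, genetic_code = "1") {
  mode <- match.arg(mode)
  if (nrow(genes) == 0L) {
    abort("No usable genes for species profile.", class = "camphy_empty_species")
  }
  species <- species %||% unique(genes$species)
  if (length(species) != 1L) {
    abort("Records from more than one species; supply `species` or split first.")
  }
  if (!"motif" %in% names(genes)) {
    genes <- gene_motifs(genes, mode, genetic_code)
  }
  tab <- table(genes$motif)
  counts <- setNames(as.integer(tab), names(tab))
  new_cam_profile(species, counts, nrow(genes), mode)
}

#' Build profiles for several species at once
#'
#' @param genes Tibble of gene records spanning one or more species.
#' @inheritParams gene_motifs
#' @return Named list of `cam_profile` objects, in order of first
#'   appearance of each species.
#' @export
species_profiles <- function(genes, mode = c("codon", "amino_acid"),
                             genetic_code = "1") {
  mode <- match.arg(mode)
  genes <- gene_motifs(genes, mode, genetic_code)
  split_idx <- split(seq_len(nrow(genes)), factor(genes$species,
                                                  levels = unique(genes$species)))
  profiles <- lapply(names(split_idx), function(sp) {
    build_species_profile(genes[split_idx[[sp]], ], mode, species = sp)
  })
  setNames(profiles, names(split_idx))
}

#' Read one species FASTA into a motif profile
#'
#' Convenience wrapper chaining [read_cds()], [select_longest_isoforms()]
#' (optional), [filter_records()] and [build_species_profile()].
#'
#' @inheritParams read_cds
#' @inheritParams gene_motifs
#' @param collapse_isoforms Keep only the longest isoform per `gene=`
#'   identifier.
#' @param drop_exceptions,drop_partials Passed to [filter_records()].
#' @param quiet Suppress progress messages.
#' @return A `cam_profile`.
#' @export
read_species_profile <- function(path, mode = c("codon", "amino_acid"),
                                 species = NULL, genetic_code = "1",
                                 collapse_isoforms = FALSE,
                                 drop_exceptions = TRUE,
                                 drop_partials = FALSE,
                                 quiet = TRUE) {
  mode <- match.arg(mode)
  genes <- read_cds(path, species = species)
  if (collapse_isoforms) genes <- select_longest_isoforms(genes)
  genes <- filter_records(genes, drop_exceptions, drop_partials, quiet = quiet)
  if (!quiet) {
    inform(sprintf("%s: %d gene(s) after filtering.",
                   unique(genes$species), nrow(genes)))
  }
  build_species_profile(genes, mode, species = species)
}

#' @export
print.cam_profile <- function(x, ...) {
  cat(sprintf("<cam_profile> %s: %d unique %s motif(s) from %d gene(s)\n",
              x$species, length(x$motifs),
              if (x$mode == "codon") "codon" else "amino-acid", x$n_genes))
  invisible(x)
}

#' Tidy a species motif profile
#'
#' @param x A `cam_profile`.
#' @param ... Unused.
#' @return A tibble with one row per unique motif: `species`, `motif`,
#'   `motif_size`, `count`.
#' @method tidy cam_profile
#' @export
tidy.cam_profile <- function(x, ...) {
  tibble(
    species = x$species,
    motif = x$motifs,
    motif_size = motif_size(x$motifs),
    count = unname(x$counts)
  )
}

#' @rdname tidy.cam_profile
#' @return For `glance()`: a one-row tibble with `species`, `mode`,
#'   `n_genes`, `n_unique_motifs`, `mean_size`.
#' @method glance cam_profile
#' @export
glance.cam_profile <- function(x, ...) {
  sizes <- motif_size(x$motifs)
  tibble(
    species = x$species,
    mode = x$mode,
    n_genes = x$n_genes,
    n_unique_motifs = length(x$motifs),
    mean_size = sum(sizes * x$counts) / x$n_genes
  )
}
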