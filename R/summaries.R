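profile_list <- function(profiles) {
  if (inherits(profiles, "cam_profile")) profiles <- list(profiles)
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, logical(1), "cam_profile")))
  modes <- unique(vapply(profiles, function(p) p$mode, character(1)))
  if (length(modes) != 1L) {
    abort("Profiles mix codon and amino-acid modes.",
          class = "camphy_mode_mismatch")
  }
  profiles
}

#' Motif summary statistics over species profiles
#'
#' Computes the descriptive statistics of aversion motifs across one or
#' more species: the distribution of motif sizes over genes, per-codon
#' (or per-amino-acid) aversion frequencies reported per species (the
#' fraction of a species' genes whose motif contains the symbol), the
#' repetition spectrum of motifs (how many motifs occur exactly k times
#' across all genes, within-species repeats included), and the count of
#' unique motifs in the union over species.
#'
#' @param profiles A `cam_profile` or list of them (one mode).
#' @return A `cam_motif_stats` object with elements `size_histogram`
#'   (tibble `motif_size`, `n_genes`), `per_symbol_freq` (tibble
#'   `species`, `symbol`, `frequency`), `repetition_spectrum` (tibble
#'   `occurrences`, `n_motifs`), and scalars `n_unique_motifs`,
#'   `n_genes`, `mean_size`, `sd_size`, `mode`.
#' @export
motif_stats <- function(profiles) {
  profiles <- profile_list(profiles)
  mode <- profiles[[1]]$mode
  alphabet <- if (mode == "codon") cam_codons() else cam_amino_acids()

  per_gene <- purrr::map_dfr(profiles, function(p) {
    tibble(species = p$species, motif = p$motifs,
           motif_size = motif_size(p$motifs), count = unname(p$counts))
  })
  n_genes <- sum(per_gene$count)
  size_histogram <- per_gene |>
    group_by(.data$motif_size) |>
    summarise(n_genes = sum(.data$count), .groups = "drop") |>
    arrange(.data$motif_size)
  mean_size <- sum(per_gene$motif_size * per_gene$count) / n_genes
  sd_size <- if (n_genes > 1L) {
    sqrt(sum(per_gene$count * (per_gene$motif_size - mean_size)^2) /
           (n_genes - 1L))
  } else {
    0
  }

  per_symbol_freq <- purrr::map_dfr(profiles, function(p) {
    members <- lapply(p$motifs, parse_motif)
    freq <- vapply(alphabet, function(sym) {
      sum(p$counts[vapply(members, function(m) sym %in% m, logical(1))]) /
        p$n_genes
    }, numeric(1))
    tibble(species = p$species, symbol = alphabet, frequency = unname(freq))
  })

  totals <- per_gene |>
    group_by(.data$motif) |>
    summarise(total = sum(.data$count), .groups = "drop")
  repetition_spectrum <- totals |>
    count(.data$total, name = "n_motifs") |>
    dplyr::rename(occurrences = "total") |>
    arrange(.data$occurrences)

  structure(
    list(size_histogram = size_histogram,
         per_symbol_freq = per_symbol_freq,
         repetition_spectrum = repetition_spectrum,
         n_unique_motifs = nrow(totals),
         n_genes = n_genes,
         mean_size = mean_size,
         sd_size = sd_size,
         mode = mode),
    class = "cam_motif_stats"
  )
}

#' Shared versus singleton motifs
#'
#' A motif is a singleton when it occurs in exactly one gene across all
#' species (within-species repeats count); it is shared otherwise. The
#' two counts partition the unique-motif set.
#'
#' @inheritParams motif_stats
#' @return A one-row tibble with `n_shared`, `n_singleton`,
#'   `n_unique_motifs`.
#' @export
shared_vs_unique <- function(profiles) {
  profiles <- profile_list(profiles)
  totals <- purrr::map_dfr(profiles, function(p) {
    tibble(motif = p$motifs, count = unname(p$counts))
  }) |>
    group_by(.data$motif) |>
    summarise(total = sum(.data$count), .groups = "drop")
  tibble(
    n_shared = sum(totals$total > 1L),
    n_singleton = sum(totals$total == 1L),
    n_unique_motifs = nrow(totals)
  )
}

#' @export
print.cam_motif_stats <- function(x, ...) {
  cat(sprintf(
    "<cam_motif_stats> %s mode: %d genes, %d unique motifs, mean size %.4f (sd %.4f)\n",
    x$mode, x$n_genes, x$n_unique_motifs, x$mean_size, x$sd_size))
  invisible(x)
}

#' Tidy motif summary statistics
#'
#' @param x A `cam_motif_stats` object.
#' @param which Which table to return: the motif-size histogram, the
#'   per-species aversion frequency per symbol, or the repetition
#'   spectrum.
#' @param ... Unused.
#' @return A tibble (see [motif_stats()] for columns).
#' @method tidy cam_motif_stats
#' @export
tidy.cam_motif_stats <- function(x, which = c("size_histogram",
                                              "per_symbol_freq",
                                              "repetition_spectrum"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @rdname tidy.cam_motif_stats
#' @method glance cam_motif_stats
#' @export
glance.cam_motif_stats <- function(x, ...) {
  tibble(
    mode = x$mode,
    n_genes = x$n_genes,
    n_unique_motifs = x$n_unique_motifs,
    mean_size = x$mean_size,
    sd_size = x$sd_size,
    genes_per_motif = x$n_genes / x$n_unique_motifs
  )
}

#' Write motif summary tables as TSV
#'
#' One file per statistic: `size_histogram.tsv`, `per_symbol_freq.tsv`,
#' `repetition_spectrum.tsv`, plus `summary.tsv` with the scalar
#' statistics of [glance.cam_motif_stats()].
#'
#' @param x A `cam_motif_stats` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_motif_stats <- function(x, dir) {
  stopifnot(inherits(x, "cam_motif_stats"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(tbl, name) {
    utils::write.table(tbl, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(x$size_histogram, "size_histogram.tsv")
  tsv(x$per_symbol_freq, "per_symbol_freq.tsv")
  tsv(x$repetition_spectrum, "repetition_spectrum.tsv")
  tsv(glance(x), "summary.tsv")
  invisible(dir)
}
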