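#' Plot a distance matrix as a heatmap
#'
#' @param object A `cam_dist` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cam_dist
#' @export
autoplot.cam_dist <- function(object, ...) {
  labels <- rownames(object)
  long <- as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(long) <- c("species_a", "species_b", "distance")
  long |>
    mutate(species_a = factor(.data$species_a, levels = labels),
           species_b = factor(.data$species_b, levels = rev(labels))) |>
    ggplot2::ggplot(ggplot2::aes(.data$species_a, .data$species_b,
                                 fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot motif summary statistics
#'
#' @param object A `cam_motif_stats` object.
#' @param which `"size_histogram"` (motif sizes over genes),
#'   `"per_symbol_freq"` (per-species aversion frequency by symbol) or
#'   `"repetition_spectrum"` (log-scaled motif repetition counts).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cam_motif_stats
#' @export
autoplot.cam_motif_stats <- function(object,
                                     which = c("size_histogram",
                                               "per_symbol_freq",
                                               "repetition_spectrum"),
                                     ...) {
  which <- match.arg(which)
  if (which == "size_histogram") {
    ggplot2::ggplot(object$size_histogram,
                    ggplot2::aes(.data$motif_size, .data$n_genes)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "codons averted per gene", y = "genes") +
      ggplot2::theme_minimal()
  } else if (which == "per_symbol_freq") {
    ggplot2::ggplot(object$per_symbol_freq,
                    ggplot2::aes(.data$symbol, .data$frequency)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = NULL, y = "fraction of genes averting") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(
        angle = 90, vjust = 0.5, size = 6))
  } else {
    ggplot2::ggplot(object$repetition_spectrum,
                    ggplot2::aes(.data$occurrences, log(.data$n_motifs))) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "times a motif is repeated",
                    y = "log(number of motifs)") +
      ggplot2::theme_minimal()
  }
}
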