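# ggplot2 display helpers for the main result types.

#' Plot an intron incidence matrix
#'
#' Genes by alignment column, tiles colored by intron phase; shared
#' positions appear as vertical runs.
#'
#' @param object An `intron_incidence`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intron_incidence <- function(object, ...) {
  genes <- attr(object, "genes")
  df <- as_tibble(object)
  df$gene_id <- factor(df$gene_id, levels = rev(genes))
  df$phase <- factor(df$phase, levels = 0:2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alignment_column,
                                   y = .data$gene_id,
                                   fill = .data$phase)) +
    ggplot2::geom_tile(width = 3, height = 0.8) +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(x = "alignment column (nt)", y = NULL, fill = "phase") +
    ggplot2::theme_minimal()
}

#' Plot per-group intron phase counts
#'
#' @param object A `phase_stats` tibble from [tabulate_phase_stats()].
#' @param ... Unused.
#' @return A ggplot (stacked bars of phase counts per group; the Total
#'   row is omitted).
#' @export
autoplot.phase_stats <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$group != "Total", ]
  long <- tidyr::pivot_longer(df, c("phase0", "phase1", "phase2"),
                              names_to = "phase", values_to = "n",
                              names_prefix = "phase")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$n,
                                     fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "introns", fill = "phase") +
    ggplot2::theme_minimal()
}

#' Diagram of exon/intron structures
#'
#' Exons as boxes on the mRNA coordinate axis, intron positions as marks,
#' in the style of comparative gene-structure figures.
#'
#' @param structures A list of `gene_structure` objects.
#' @return A ggplot.
#' @export
plot_gene_structure <- function(structures) {
  feat <- structure_table(structures)
  genes <- vapply(structures, `[[`, character(1), "gene_id")
  ex <- feat[feat$feature == "exon", ]
  iv <- feat[feat$feature == "intron", ]
  ex$y <- match(ex$gene_id, rev(genes))
  iv$y <- match(iv$gene_id, rev(genes))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = ex,
                       ggplot2::aes(xmin = .data$genomic_start,
                                    xmax = .data$genomic_end,
                                    ymin = .data$y - 0.3,
                                    ymax = .data$y + 0.3),
                       fill = "grey60", color = "grey20") +
    ggplot2::scale_y_continuous(breaks = seq_along(genes),
                                labels = rev(genes)) +
    ggplot2::labs(x = "genomic position (nt)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(iv) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = iv,
      ggplot2::aes(x = .data$genomic_start, xend = .data$genomic_end,
                   y = .data$y, yend = .data$y),
      color = "grey35", linetype = "11")
  }
  p
}
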