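#' Plot a locus gene map
#'
#' Genes drawn along the chromosome coordinate, coloured by functionality
#' and shaped by gene type; assembly gaps shown as grey bands.
#'
#' @param annotation an `ig_annotation`.
#' @return A ggplot object.
#' @export
plot_locus_map <- function(annotation) {
  stopifnot(inherits(annotation, "ig_annotation"))
  g <- annotation$genes |>
    mutate(mid = (.data$start + .data$end) / 2)
  p <- ggplot2::ggplot(g)
  if (nrow(annotation$gaps)) {
    p <- p + ggplot2::geom_rect(
      data = annotation$gaps,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85")
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$gene_type, yend = .data$gene_type,
                   colour = .data$functionality),
      linewidth = 4) +
    ggplot2::scale_colour_manual(values = c(functional = "#2e7d32",
                                            ORF = "#f9a825",
                                            pseudogene = "#c62828")) +
    ggplot2::labs(
      title = sprintf("%s %s locus (%s)", annotation$region$assembly_id,
                      annotation$region$locus,
                      annotation$region$orientation),
      x = sprintf("%s position (bp)", annotation$region$seq_id),
      y = "gene type") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_locus_map
#' @param object an `ig_annotation` (autoplot method).
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ig_annotation <- function(object, ...) plot_locus_map(object)

#' Plot a gene presence matrix across assemblies
#'
#' Tile plot of gene presence by assembly, with gap-masked absences
#' distinguished from confirmed absences.
#'
#' @param comparison an `ig_comparison` or `ig_presence` object.
#' @return A ggplot object.
#' @export
plot_presence_matrix <- function(comparison) {
  pm <- if (inherits(comparison, "ig_comparison")) comparison$presence
  else comparison
  stopifnot(inherits(pm, "ig_presence"))
  long <- pm$long |>
    mutate(state = case_when(
      .data$present ~ "present",
      .data$gap_masked ~ "gap (no evidence)",
      TRUE ~ "absent"),
      gene_name = factor(.data$gene_name, levels = rev(pm$gene_names)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$assembly_id,
                                     y = .data$gene_name,
                                     fill = .data$state)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(present = "#1565c0",
                                          absent = "#c62828",
                                          `gap (no evidence)` = "grey70")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = paste(pm$locus, "gene presence")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' @rdname plot_presence_matrix
#' @param object an `ig_comparison` (autoplot method).
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ig_comparison <- function(object, ...) plot_presence_matrix(object)
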