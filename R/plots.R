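#' Heat map of disease by cell-type associations
#'
#' Tiles are shaded by `-log10` of the adjusted P value (computed by global
#' BH adjustment when a `q_value` column is absent); darker tiles mark
#' stronger associations.
#'
#' @param object An `association_test` tibble.
#' @param fdr Threshold drawn as the midpoint annotation (default 0.1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.association_test <- function(object, fdr = 0.1, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  if (!"q_value" %in% colnames(df)) df$q_value <- bh_adjust(df$p_value)
  df$strength <- -log10(df$q_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$disease,
                                   fill = .data$strength)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 name = expression(-log[10](q))) +
    ggplot2::labs(x = "cell type", y = "disease",
                  title = paste0("Associations (", attr(object, "method"),
                                 " test)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a diseasome
#'
#' Diseases are laid out on a circle (deterministic) and edges shaded by
#' correlation strength.
#'
#' @param object A `diseasome` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diseasome <- function(object, ...) {
  diseases <- object$vertices$disease
  angle <- 2 * pi * (seq_along(diseases) - 1L) / length(diseases)
  layout <- tibble::tibble(disease = diseases,
                           x = cos(angle), y = sin(angle))
  edges <- dplyr::left_join(object$edges,
                            dplyr::rename(layout, x0 = "x", y0 = "y"),
                            by = c(from = "disease"))
  edges <- dplyr::left_join(edges,
                            dplyr::rename(layout, x1 = "x", y1 = "y"),
                            by = c(to = "disease"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, alpha = .data$correlation),
      color = "steelblue"
    ) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = 1.08 * .data$x, y = 1.08 * .data$y,
                                    label = .data$disease), size = 2.6) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Cell-type-based diseasome")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
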