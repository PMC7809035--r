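#' Bar plot of module enrichment
#'
#' -log10 enrichment p per module with the Bonferroni threshold line.
#'
#' @param enr tibble from [enrich_modules()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enr) {
  ggplot2::ggplot(enr, ggplot2::aes(stats::reorder(.data$module, -log10(.data$p)),
                                    -log10(.data$p),
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(enr$bonferroni_threshold[1]),
                        linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey60"),
                               name = "enriched") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Ternary plot of cell-type coordinates
#'
#' Projects simplex coordinates from [ternary_coordinates()] into the
#' plane and draws one point per gene, optionally colored by module.
#'
#' @param coords tibble from [ternary_coordinates()] (gene + 3 coordinate
#'   columns).
#' @param color optional vector (e.g. module labels) aligned with rows.
#' @return A ggplot object.
#' @export
plot_ternary <- function(coords, color = NULL) {
  axes <- setdiff(names(coords), "gene")
  stopifnot(length(axes) == 3L)
  a <- coords[[axes[1]]]; b <- coords[[axes[2]]]; c_ <- coords[[axes[3]]]
  df <- tibble(x = b + c_ / 2, y = c_ * sqrt(3) / 2, gene = coords$gene)
  if (!is.null(color)) df$color <- color
  tri <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, color = "grey40") +
    ggplot2::annotate("text", x = c(0, 1, 0.5), y = c(-0.04, -0.04, sqrt(3) / 2 + 0.04),
                      label = axes, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (is.null(color)) gg + ggplot2::geom_point(alpha = 0.6, size = 1)
  else gg + ggplot2::geom_point(ggplot2::aes(color = .data$color), size = 1) +
    ggplot2::labs(color = NULL)
}

#' Compactness distributions by marker group
#'
#' Per-subject boxplots of cell compactness split by marker positivity.
#'
#' @param cells per-cell tibble with `subject_id`, `compactness` and a
#'   logical group column.
#' @param group group column name.
#' @return A ggplot object.
#' @export
plot_compactness <- function(cells, group = "positive_marker") {
  ggplot2::ggplot(cells, ggplot2::aes(.data$subject_id, .data$compactness,
                                      fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac"),
                               name = "marker+") +
    ggplot2::labs(x = NULL, y = "compactness") +
    ggplot2::theme_minimal()
}
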