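#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_abline geom_tile
#'   geom_smooth labs scale_fill_brewer theme_minimal
NULL

#' Stacked composition bars for abundance profiles
#'
#' @param object abundance profile tibble (one or more samples).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.abundance_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$sample_id, y = .data$relative_abundance,
                     fill = .data$clade)) +
    geom_col() +
    labs(x = NULL, y = "relative abundance (%)", fill = NULL) +
    theme_minimal()
}

#' Presence/absence heatmap of a pangenome
#'
#' @param object a `pangenome`.
#' @param max_clusters clusters shown (most variable first) to keep the
#'   panel readable.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pangenome <- function(object, max_clusters = 200, ...) {
  long <- tidy(object)
  variab <- long |>
    group_by(.data$cluster_id) |>
    summarise(v = var(.data$present), .groups = "drop") |>
    arrange(desc(.data$v)) |>
    slice_head(n = max_clusters)
  long |>
    filter(.data$cluster_id %in% variab$cluster_id) |>
    ggplot(aes(x = .data$genome_id, y = .data$cluster_id,
               fill = factor(.data$present))) +
    geom_tile() +
    labs(x = NULL, y = NULL, fill = "present") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}

#' Scatter plot of computational vs qPCR fractions with the fitted line
#'
#' @param object an `agreement` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.agreement <- function(object, ...) {
  ggplot(object$data, aes(x = .data$fraction_comp, y = .data$fraction_qpcr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    geom_point() +
    labs(x = "computational share", y = "qPCR share",
         subtitle = sprintf("R² = %.3f, slope = %.3f", object$r_squared,
                            object$slope)) +
    theme_minimal()
}

#' Plot a neighbor-joining strain tree
#'
#' @param x a `submarker_tree` (newick string with attached `phylo`).
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.submarker_tree <- function(x, ...) {
  ape::plot.phylo(attr(x, "phylo"), ...)
  invisible(x)
}
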