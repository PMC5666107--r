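#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a marginal reconstruction
#'
#' Stacked per-node state probabilities, internal nodes ordered by age (the
#' tabular analogue of per-node pie charts on the tree).
#'
#' @param object An `asr` object from [marginal_asr()].
#' @param internal_only Drop tip rows (default).
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.asr <- function(object, internal_only = TRUE, ...) {
  df <- tibble::as_tibble(object)
  if (internal_only) df <- df[!df$is_tip, , drop = FALSE]
  df$node_lab <- sprintf("node %d (%.1f Ma)", df$node, df$age_ma)
  df$node_lab <- stats::reorder(df$node_lab, df$age_ma)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_lab, y = .data$probability,
                                   fill = .data$state)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior probability",
                  fill = "state",
                  title = sprintf("Marginal ancestral states: %s",
                                  attr(object, "char_name"))) +
    ggplot2::theme_minimal()
}

#' Plot a site-rate category assignment
#'
#' Histogram of assigned gamma categories, faceted by gene when the
#' assignment covers several partitions.
#'
#' @param object A `site_rate_assignment` from [assign_site_categories()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.site_rate_assignment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$category))) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "assigned gamma rate category (1 = slowest)",
                  y = "sites") +
    ggplot2::theme_minimal()
  if (length(unique(df$gene[!is.na(df$gene)])) > 1) {
    p <- p + ggplot2::facet_wrap(~gene)
  }
  p
}
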