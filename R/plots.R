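#' Plot a comorbidity network
#'
#' Force-directed layout with node size proportional to degree, the classic
#' view in which hub diseases stand out; optionally coloured by module.
#'
#' @param object A `comorbidity_network`.
#' @param partition Optional `module_partition` for node colours.
#' @param layout_seed Seed for the layout (default 1).
#' @param label_top Label the `label_top` highest-degree nodes (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comorbidity_network <- function(object, partition = NULL,
                                         layout_seed = 1L, label_top = 10L,
                                         ...) {
  g <- object$graph
  if (igraph::vcount(g) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty network") +
             ggplot2::theme_void())
  }
  xy <- with_local_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- tibble(code = igraph::V(g)$name,
                  x = xy[, 1], y = xy[, 2],
                  degree = as.integer(igraph::degree(g)))
  if (!is.null(partition)) {
    m <- setNames(partition$module, partition$code)
    nodes$module <- factor(m[nodes$code])
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  pos <- setNames(seq_len(nrow(nodes)), nodes$code)
  edges <- tibble(x = nodes$x[pos[el[, 1]]], y = nodes$y[pos[el[, 1]]],
                  xend = nodes$x[pos[el[, 2]]], yend = nodes$y[pos[el[, 2]]])
  lab <- nodes[order(-nodes$degree), ][seq_len(min(label_top, nrow(nodes))), ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linewidth = 0.2, alpha = 0.3, colour = "grey50")
  p <- if (is.null(partition)) {
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(.data$x, .data$y, size = .data$degree),
                            colour = "firebrick", alpha = 0.8)
  } else {
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(.data$x, .data$y, size = .data$degree,
                                         colour = .data$module), alpha = 0.8)
  }
  p +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(.data$x, .data$y, label = .data$code),
                       size = 2.6, vjust = -1) +
    ggplot2::scale_size_continuous(range = c(0.5, 6)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "degree", colour = "module")
}

#' Plot prevalence-by-age profiles
#'
#' Line plot of group prevalence across age brackets, faceted by sex — the
#' standard view of, e.g., congenital malformations dominating childhood
#' while ischemic disease rises with age.
#'
#' @param prevalence Output of [prevalence_summary()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$age_bracket, y = .data$percent,
                               colour = .data$group,
                               group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(x = "age bracket", y = "% of records in cell") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot module flow composition
#'
#' Bar chart of total PageRank flow per module, annotated with the module's
#' label disease.
#'
#' @param object A `module_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_partition <- function(object, ...) {
  mods <- attr(object, "modules")
  ggplot2::ggplot(mods,
                  ggplot2::aes(x = factor(.data$module), y = .data$flow)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "module", y = "total visit rate") +
    ggplot2::theme_minimal()
}

#' Plot pathway enrichment
#'
#' Lollipop chart of `-log10(q)` for the strongest pathways.
#'
#' @param object An `enrichment_result`.
#' @param top_n Pathways shown (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top_n = 10L, ...) {
  df <- head(as_tibble(object), top_n)
  df$pathway <- factor(df$pathway, levels = rev(df$pathway))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$q, 1e-300)),
                                   y = .data$pathway)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = -log10(pmax(.data$q, 1e-300)),
                                       yend = .data$pathway), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2.5) +
    ggplot2::labs(x = expression(-log[10](q)), y = NULL, colour = "q < alpha") +
    ggplot2::theme_minimal()
}
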