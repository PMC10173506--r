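# ggplot2 visual summaries of the main result types.

#' Niche breadth versus abundance scatter
#'
#' Each point is an ASV: mean relative abundance (log scale) against
#' Levins' B, colored by niche category, with the category cutoffs drawn
#' as horizontal lines.
#'
#' @param profiles Output of [niche_profiles()].
#' @return A ggplot object.
#' @export
plot_niche_breadth <- function(profiles) {
  thr <- attr(profiles, "thresholds")
  p <- ggplot2::ggplot(
    dplyr::filter(profiles, !is.na(.data$b)),
    ggplot2::aes(x = .data$mean_rel_abund, y = .data$b,
                 colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean relative abundance", y = "niche breadth (B)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = unname(thr),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Zi-Pi role plot
#'
#' Within-module degree against among-module connectivity with the role
#' thresholds; the four quadrants are the peripheral / connector /
#' module-hub / network-hub roles.
#'
#' @param roles Output of [node_roles()].
#' @param z_threshold,p_threshold Role thresholds (defaults 2.5 / 0.62).
#' @return A ggplot object.
#' @export
plot_zipi <- function(roles, z_threshold = 2.5, p_threshold = 0.62) {
  ggplot2::ggplot(roles, ggplot2::aes(x = .data$p_among, y = .data$z_within,
                                      colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = z_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = p_threshold, linetype = "dashed") +
    ggplot2::labs(x = "among-module connectivity (Pi)",
                  y = "within-module degree (Zi)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Module distribution patterns along the gradient
#'
#' One line per module: the feature-scaled mean member abundance per
#' sample, with samples ordered by a metadata covariate (elevation by
#' default) when metadata is supplied.
#'
#' @param patterns Long tibble from [module_patterns()].
#' @param metadata Optional metadata tibble used to order samples.
#' @param order_by Covariate to order samples by (default "elevation").
#' @return A ggplot object.
#' @export
plot_module_patterns <- function(patterns, metadata = NULL, order_by = "elevation") {
  df <- patterns
  if (!is.null(metadata) && order_by %in% names(metadata)) {
    ord <- metadata$sample_id[order(metadata[[order_by]])]
    df$sample_rank <- match(df$sample_id, ord)
    xlab <- paste0("sample rank by ", order_by)
  } else {
    df$sample_rank <- match(df$sample_id, unique(df$sample_id))
    xlab <- "sample"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_rank, y = .data$pattern,
                                   colour = factor(.data$module))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = xlab, y = "module distribution pattern",
                  colour = "module") +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout (fixed seed) with nodes colored by niche
#' category (environment nodes highlighted) and edges drawn faintly.
#'
#' @param object A `conetwork`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.conetwork <- function(object, seed = 1, ...) {
  g <- object$graph
  xy <- with_seed_(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  if (!("category" %in% names(nodes))) nodes$category <- nodes$kind
  nodes$category[nodes$kind == "env"] <- "environment"
  edges <- object$edges
  edges$x <- nodes$x[match(edges$source, nodes$id)]
  edges$y <- nodes$y[match(edges$source, nodes$id)]
  edges$xend <- nodes$x[match(edges$target, nodes$id)]
  edges$yend <- nodes$y[match(edges$target, nodes$id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey80", linewidth = 0.2) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$category,
                                     shape = .data$kind), size = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, shape = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
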