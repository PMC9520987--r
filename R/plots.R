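#' Plot a causal network
#'
#' Draws the mixed graph with directed edges as arrows, undirected edges as
#' plain segments, and bidirected edges dashed; edge width scales with
#' |effect| where effects were estimated.
#'
#' @param object A `causal_network`.
#' @param layout_seed Seed for the layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.causal_network <- function(object, layout_seed = 1, ...) {
  e <- object$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$source, to = e$target),
    directed = TRUE, vertices = object$nodes)
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(node = object$nodes, x = xy[, 1], y = xy[, 2])
  seg <- e %>%
    left_join(rename(nodes, source = "node", x0 = "x", y0 = "y"),
              by = "source") %>%
    left_join(rename(nodes, target = "node", x1 = "x", y1 = "y"),
              by = "target") %>%
    mutate(width = ifelse(is.na(.data$effect), 0.4,
                          0.3 + abs(.data$effect)))
  p <- ggplot2::ggplot()
  dirseg <- filter(seg, .data$kind == "directed")
  if (nrow(dirseg)) {
    p <- p + ggplot2::geom_segment(
      data = dirseg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$width),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"), type = "closed"),
      colour = "grey30")
  }
  other <- filter(seg, .data$kind != "directed")
  if (nrow(other)) {
    p <- p + ggplot2::geom_segment(
      data = other,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = .data$kind),
      colour = "grey55")
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 7, colour = "orange") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node), size = 2.6) +
    ggplot2::scale_linewidth_identity() +
    ggplot2::scale_linetype_manual(
      values = c(undirected = "solid", bidirected = "dashed"),
      name = NULL) +
    ggplot2::theme_void()
}

#' Scree plot of polygenic factors
#'
#' @param object A [build_polygenic_factors()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polygenic_factors <- function(object, ...) {
  df <- tibble(factor = seq_along(object$variance_explained),
               variance_explained = object$variance_explained)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor,
                                   y = .data$variance_explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "polygenic factor",
                  y = "proportion of genetic variance explained") +
    ggplot2::theme_minimal()
}

#' @export
tidy.mediation_estimate <- function(x, ...) {
  est <- tibble(term = c("tau", "gamma", "beta_total", "phi"),
                estimate = c(x$tau, x$gamma, x$beta_total, x$phi))
  left_join(est, x$ses, by = "term")
}

#' @export
glance.first_stage_fit <- function(x, ...) {
  tibble(entity = x$entity, n_instruments = length(x$instrument_ids),
         r_squared = x$r_squared, f_statistic = x$f_statistic, n = x$n)
}
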