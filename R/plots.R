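#' Plot a space-sharing network
#'
#' Force-directed layout with edge width proportional to the shared-site
#' weight; a quick visual check, not a publication figure.
#'
#' @param object A `sharing_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sharing_network
#' @export
autoplot.sharing_network <- function(object, ...) {
  g <- igraph::graph_from_adjacency_matrix(object$W, mode = "undirected",
                                           weighted = TRUE)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(bat_id = rownames(object$W),
                          x = xy[, 1], y = xy[, 2])
  ed <- tidy(object)
  ed <- dplyr::left_join(ed, nodes, by = c("id_a" = "bat_id"))
  ed <- dplyr::left_join(ed, nodes, by = c("id_b" = "bat_id"),
                         suffix = c("", "_end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end,
                   yend = .data$y_end, linewidth = .data$weight),
      colour = "grey60", alpha = 0.6) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3, colour = "steelblue") +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::theme_void()
}

#' Histogram of pairwise relatedness, optionally split by season
#'
#' @param rel A `relatedness_df`.
#' @param seasons Optional named vector id -> season; within-season pairs
#'   are then coloured by season.
#' @param binwidth Histogram bin width (default 0.05).
#' @return A ggplot object.
#' @export
plot_relatedness_dist <- function(rel, seasons = NULL, binwidth = 0.05) {
  d <- tibble::as_tibble(rel[!is.na(rel$r), ])
  if (!is.null(seasons)) {
    d$season_a <- seasons[d$id_a]
    d$season_b <- seasons[d$id_b]
    d <- d[!is.na(d$season_a) & d$season_a == d$season_b, ]
    d$season <- d$season_a
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$r, fill = .data$season)) +
      ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                              position = "dodge")
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$r)) +
      ggplot2::geom_histogram(binwidth = binwidth, boundary = 0)
  }
  p + ggplot2::labs(x = "pairwise relatedness r", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Seasonal home-range boxplots
#'
#' @param homeranges Output of [home_ranges()] with a `season` column.
#' @param level Which MCP level to plot (default 95).
#' @return A ggplot object.
#' @export
plot_homerange_areas <- function(homeranges, level = 95) {
  d <- homeranges[homeranges$level == level, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$season, y = .data$area_ha)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = sprintf("MCP %d%% area (ha)", level), x = NULL) +
    ggplot2::theme_minimal()
}
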