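#' Plot an arena
#'
#' Heightfield (or habitability) raster with the region sites overlaid.
#'
#' @param object an `arena`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.arena <- function(object, ...) {
  base <- if (is.null(object$heightfield)) {
    matrix(as.numeric(object$mask), nrow(object$mask))
  } else {
    unclass(object$heightfield)
  }
  df <- raster_df(base)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(
      low = "grey10", high = "grey95",
      name = if (is.null(object$heightfield)) "habitable" else "elevation"
    ) +
    ggplot2::geom_point(
      data = object$sites,
      ggplot2::aes(x = .data$col, y = .data$row),
      colour = "white", size = 2
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col", y = "row") +
    ggplot2::theme_minimal()
}

#' Plot the trail field of a simulation state
#' @param object a `sim_state`.
#' @param what `"trail"` or `"occupancy"`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sim_state <- function(object, what = c("trail", "occupancy"), ...) {
  what <- match.arg(what)
  m <- if (what == "trail") object$trail else occupancy_matrix(object)
  df <- raster_df(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = what) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a Physarum graph with edge width proportional to incidence
#'
#' @param object a `physarum_graph` or `threshold_graph`.
#' @param layout optional tibble (`region`, `row`, `col`) with node
#'   positions (e.g. the site coordinates); defaults to a
#'   Fruchterman-Reingold layout.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.physarum_graph <- function(object, layout = NULL, ...) {
  ig <- graph_igraph(object)
  if (is.null(layout)) {
    xy <- igraph::layout_with_fr(ig)
    layout <- tibble::tibble(region = igraph::V(ig)$name,
                             col = xy[, 1], row = xy[, 2])
  }
  ed <- object$edges |>
    dplyr::left_join(layout, by = c(region_a = "region")) |>
    dplyr::rename(x = "col", y = "row") |>
    dplyr::left_join(layout, by = c(region_b = "region")) |>
    dplyr::rename(xend = "col", yend = "row")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$count),
      colour = "grey40"
    ) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$col, y = .data$row),
                        size = 3) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = .data$col, y = .data$row,
                                    label = .data$region),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2.5), name = "incidence") +
    ggplot2::theme_void()
}

#' @rdname autoplot.physarum_graph
#' @export
autoplot.threshold_graph <- autoplot.physarum_graph

#' Plot mean-degree ranking
#' @param object tibble from [mean_degree_table()].
#' @param ... unused.
#' @return A ggplot.
#' @export
plot_mean_degree <- function(object, ...) {
  object$region <- factor(object$region,
                          levels = rev(object$region[order(object$rank)]))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_degree, y = .data$region)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "mean degree over replicates", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#' @param object tibble from [weight_sweep()].
#' @param ... unused.
#' @return A ggplot of component/edge counts against the threshold.
#' @export
plot_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("theta", "n_edges", "n_components", "n_isolated")],
    -"theta", names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(theta), y = NULL) +
    ggplot2::theme_minimal()
}

raster_df <- function(m) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    col = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    value = as.vector(m)
  )
}
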