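# ggplot2 views of runs and networks.

#' Plot species abundances over time
#'
#' @param run A `gutsim_run` (or a tidy abundance tibble from
#'   [tidy.gutsim_run()]).
#' @param relative Plot relative instead of absolute abundance.
#' @return A ggplot.
#' @export
plot_abundance <- function(run, relative = FALSE) {
  long <- if (inherits(run, "gutsim_run")) tidy(run) else run
  hours <- long$t * 180 / 3600
  ggplot2::ggplot(long, ggplot2::aes(
    x = hours,
    y = if (relative) .data$rel_abundance else .data$cells,
    colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)",
                  y = if (relative) "relative abundance" else "cells",
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' @rdname plot_abundance
#' @param object A `gutsim_run`.
#' @param ... Passed to [plot_abundance()].
#' @export
autoplot.gutsim_run <- function(object, ...) plot_abundance(object, ...)

#' Plot a cross-feeding flux network
#'
#' Species and metabolite-pool nodes, edge width scaled with umol atomic
#' carbon over the aggregation window.
#'
#' @param net A [flux_network()].
#' @return A ggplot.
#' @export
plot_flux_network <- function(net) {
  g <- flux_network_graph(net)
  set.seed(1) # layout only; cosmetic determinism
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          type = igraph::V(g)$type,
                          x = xy[, 1], y = xy[, 2])
  ed <- tibble::as_tibble(as.data.frame(net))
  ed <- dplyr::left_join(ed, nodes[, c("name", "x", "y")],
                         by = c(from = "name"))
  ed <- dplyr::left_join(ed, nodes[, c("name", "x", "y")],
                         by = c(to = "name"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$umol_carbon),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, shape = .data$type),
                        size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "umol C")
}
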