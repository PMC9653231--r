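#' Plot a sweep table
#'
#' Division rate (and, when present, equilibrium nucleotide concentration)
#' against the sweep's primary axis. Log-like axes (spanning more than two
#' decades of positive values) are drawn on a log10 scale.
#'
#' @param object A `"protocell_sweep"` tibble.
#' @param y Column to draw, `"division_rate"` (default) or `"eq_n_conc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protocell_sweep <- function(object, y = "division_rate", ...) {
  axes <- attr(object, "axes")
  xvar <- names(axes)[1]
  tbl <- as_tibble(object)
  gg <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data[[xvar]], y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xvar,
                  y = if (y == "division_rate") "divisions per day"
                      else "equilibrium [N]")
  x <- tbl[[xvar]]
  if (is.numeric(x) && all(x > 0) && max(x) / min(x) > 100) {
    gg <- gg + ggplot2::scale_x_log10()
  }
  if ("pathway" %in% names(tbl) && length(unique(tbl$pathway)) > 1) {
    gg <- gg + ggplot2::aes(colour = .data$pathway)
  }
  gg
}

#' Plot an autocatalysis heat map
#'
#' Tile map of the division rate or the equilibrium nucleotide concentration
#' over the log KNN x log KCN grid.
#'
#' @param object A `"protocell_heatmap"`.
#' @param fill `"division_rate"` (default) or `"eq_n_conc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protocell_heatmap <- function(object, fill = "division_rate", ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = log10(.data$kcn), y = log10(.data$knn),
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "log10 KCN", y = "log10 KNN",
                  fill = if (fill == "division_rate") "divisions/day"
                         else "equilibrium [N]")
}

#' Plot a lineage
#'
#' Inter-division intervals against division index: the convergence of the
#' division cycle at a glance.
#'
#' @param object A `"protocell_lineage"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protocell_lineage <- function(object, ...) {
  ggplot2::ggplot(object$events,
                  ggplot2::aes(x = .data$division, y = .data$interval)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "division", y = "inter-division interval (days)")
}
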