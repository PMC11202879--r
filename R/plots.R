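# ggplot2 views of grids and evaluation reports.

#' Heatmap of a posterior-pole grid
#'
#' Renders one eye/layer sector map as a tile plot in grid coordinates
#' (row 1 at the top, i.e. superior retina up). For corrected grids the
#' signed deviation is shown on a diverging scale centered at zero — the
#' numeric analog of the color-coded deviation maps read clinically —
#' otherwise absolute thickness.
#'
#' @param grids A grid tibble (raw or corrected).
#' @param patient_id,eye,layer Selectors for a single grid.
#' @return A ggplot object.
#' @export
plot_sector_map <- function(grids, patient_id, eye, layer) {
  g <- dplyr::filter(grids, .data$patient_id == !!patient_id,
                     .data$eye == !!eye, .data$layer == !!layer)
  if (nrow(g) == 0) stop("no matching grid", call. = FALSE)
  corrected <- "deviation_um" %in% names(g)
  fill_var <- if (corrected) "deviation_um" else "thickness_um"
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data[[fill_var]])) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_y_reverse(breaks = unique(g$row)) +
    ggplot2::scale_x_continuous(breaks = unique(g$col)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = paste0(patient_id, " ", eye, " ", layer,
                     if (corrected) " (deviation)" else " (thickness)"),
      x = "column", y = "row",
      fill = if (corrected) "Δ µm" else "µm"
    ) +
    ggplot2::theme_minimal()
  if (corrected) {
    p + ggplot2::scale_fill_gradient2(low = "#7f0000", mid = "white",
                                      high = "#2166ac", midpoint = 0)
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}

#' Plot the accuracy statistics of an evaluation
#'
#' One point per comparison and statistic (sensitivity, specificity, PPV,
#' NPV), faceted by analysis level.
#'
#' @param object An `hm_eval` from [run_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hm_eval <- function(object, ...) {
  long <- object$report |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "ppv", "npv"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$comparison,
                                     color = .data$statistic)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$level), scales = "free_y",
                        space = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "value", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
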