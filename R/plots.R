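#' Plot the morpho-functional space
#'
#' Entity positions on the first two functional axes, sized by
#' relative-abundance weights when supplied, with the eight trait vectors
#' overlaid as arrows from the origin (scaled to the coordinate range).
#'
#' @param object A [functional_space()] object.
#' @param weights Optional tibble with `fe_id` and `weight` (e.g. one
#'   sample of [relative_abundances()]); absent entities are drawn hollow.
#' @param vector_scale Multiplier applied to the trait-vector loadings for
#'   display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.functional_space <- function(object, weights = NULL,
                                      vector_scale = NULL, ...) {
  ax <- axis_cols(object)[1:2]
  pts <- fe_coordinates(object)
  if (!is.null(weights)) {
    pts <- dplyr::left_join(pts, weights[c("fe_id", "weight")], by = "fe_id")
  }
  tv <- object$trait_vectors
  if (is.null(vector_scale)) {
    vector_scale <- 0.9 * max(abs(as.matrix(pts[ax])))
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data[[ax[1]]],
                                         y = .data[[ax[2]]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey70")
  if (!is.null(weights)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(size = .data$weight),
                                 alpha = 0.7, na.rm = TRUE)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::geom_segment(
      data = tv,
      ggplot2::aes(x = 0, y = 0,
                   xend = .data[[ax[1]]] * vector_scale,
                   yend = .data[[ax[2]]] * vector_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "steelblue") +
    ggplot2::geom_text(
      data = tv,
      ggplot2::aes(x = .data[[ax[1]]] * vector_scale * 1.08,
                   y = .data[[ax[2]]] * vector_scale * 1.08,
                   label = .data$trait),
      colour = "steelblue", size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot yearly index trajectories
#'
#' Mean +/- standard error of each index through time, one panel per index
#' (free y scales), from the long table produced by [yearly_summary()].
#'
#' @param yearly Long tibble with `year`, `index`, `mean`, `se`.
#' @return A ggplot object.
#' @export
plot_index_trajectories <- function(yearly) {
  ggplot2::ggplot(yearly, ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.3) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(y = "mean ± SE") +
    ggplot2::theme_minimal()
}

#' Plot community-weighted trait-mean trajectories
#'
#' Per-trait percent contribution through time from the long table produced
#' by [cwm()]; per-transect tables are summarized to mean +/- SE first.
#'
#' @param cwm_tbl Long tibble with `year`, `trait`, `cwm` (and optionally
#'   `transect`).
#' @return A ggplot object.
#' @export
plot_cwm <- function(cwm_tbl) {
  summ <- cwm_tbl |>
    dplyr::group_by(.data$year, .data$trait) |>
    dplyr::summarise(
      se = if (dplyr::n() > 1) stats::sd(.data$cwm) / sqrt(dplyr::n()) else 0,
      cwm = mean(.data$cwm), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$year, y = .data$cwm)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$cwm - .data$se,
                                          ymax = .data$cwm + .data$se),
                             size = 0.3) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(y = "CWM (% contribution)") +
    ggplot2::theme_minimal()
}
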