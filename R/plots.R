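#' Plot raster layers
#'
#' Tile maps in map coordinates with `coord_equal()`; continuous layers get
#' a viridis fill, categorical layers a discrete fill using legend labels
#' when declared.
#'
#' @param object a `pm_continuous` or `pm_categorical` layer
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.pm_continuous <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pm_continuous
#' @export
autoplot.pm_categorical <- function(object, ...) {
  d <- as_tibble(object)
  if (!is.null(object$legend)) {
    lab <- names(object$legend)[match(d$value, object$legend)]
    d$value <- factor(ifelse(is.na(lab), as.character(d$value), lab),
                      levels = unique(c(names(object$legend),
                                        as.character(d$value))))
  } else {
    d$value <- factor(d$value)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_d(drop = TRUE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot per-variable importance of a maxent model
#'
#' @param importance output of [variable_importance()]
#' @return a ggplot bar chart of the percentage columns present
#' @export
plot_importance <- function(importance) {
  cols <- intersect(c("contribution", "permutation"), names(importance))
  d <- tidyr::pivot_longer(importance[, c("variable", cols)], -"variable",
                           names_to = "measure", values_to = "pct")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$variable, .data$pct),
                                  y = .data$pct, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal()
}
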