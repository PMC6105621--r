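# ggplot2 display methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an axial slice of a connectivity Z map
#'
#' @param object An `fc_map`.
#' @param slice Axial (third-axis) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_map <- function(object, slice = NULL, ...) {
  d <- dim(object$z)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$z <- as.numeric(object$z[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "grey95",
                                  high = "firebrick", na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Seed connectivity Z, axial slice %d", slice),
                  fill = "Z") +
    ggplot2::theme_minimal()
}

#' Plot a marker-by-outcome correlation grid
#'
#' @param object Output of [correlation_report()].
#' @param ... Unused.
#' @return A ggplot tile map of r values, large correlations outlined.
#' @export
autoplot.correlation_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$outcome, .data$marker, fill = .data$r)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$r), "", sprintf("%.2f", .data$r)),
      fontface = ifelse(.data$large, "bold", "plain"))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  high = "firebrick", na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Plot the laterality-vs-coupling recovery curve
#'
#' @param object Output of [phantom_li_experiment()].
#' @param ... Unused.
#' @return A ggplot of LI against planted interhemispheric coupling.
#' @export
autoplot_li_experiment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$coupling, .data$li_s1)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line", color = "firebrick") +
    ggplot2::labs(x = "planted S1 interhemispheric coupling",
                  y = "recovered laterality index (S1 seed)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
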