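#' Plot a tomogram slice
#'
#' Raster plot of one z slice with physical axes, coloured by RI.
#'
#' @param object An [ri_tomogram()].
#' @param z Slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ri_tomogram
#' @export
autoplot.ri_tomogram <- function(object, z = NULL, ...) {
  d <- dim(object$values)
  z <- z %||% ((d[1] + 1L) %/% 2L)
  df <- expand.grid(y = seq_len(d[2]), x = seq_len(d[3]))
  df$ri <- as.vector(object$values[z, , ])
  df$y_um <- df$y * object$spacing[2]
  df$x_um <- df$x * object$spacing[3]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$ri)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "RI") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (µm)", y = "y (µm)",
      title = sprintf("RI tomogram, z slice %d/%d", z, d[1])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-band morphometric panel
#'
#' Bar panel of the per-compartment statistics, facetted by statistic.
#'
#' @param object An `ri_analysis` from [run_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ri_analysis
#' @export
autoplot.ri_analysis <- function(object, ...) {
  long <- tidy(object)
  long <- long[!long$statistic %in% c("ri_min", "ri_max", "threshold_ri"), ]
  band_cols <- stats::setNames(
    ifelse(is.na(object$bands$color), "grey40", object$bands$color),
    object$bands$label)
  ggplot2::ggplot(long, ggplot2::aes(.data$label, .data$value,
                                     fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = band_cols) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}
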