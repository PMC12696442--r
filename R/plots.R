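#' Plot one slice of a stack
#'
#' Raster view of a binarized slice: solid, pore and outside-domain
#' background in three shades.
#'
#' @param object A `slice_stack`.
#' @param slice Slice index (middle slice by default).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slice_stack <- function(object, slice = NULL, ...) {
  slice <- slice %||% ((n_slices(object) + 1L) %/% 2L)
  sl <- object$data[, , slice]
  df <- tibble::tibble(
    row = as.vector(row(sl)),
    col = as.vector(col(sl)),
    phase = factor(ifelse(is.na(sl), "outside",
                          ifelse(sl == 1L, "solid", "pore")),
                   levels = c("solid", "pore", "outside"))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(solid = "grey20", pore = "white",
                                          outside = "grey75")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice %d (%.4g um/px)", slice,
                                  object$pixel_size),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the pore-size distribution of a morphometry result
#'
#' Histogram of per-pore Equivalent Circular Diameters with the mean marked.
#'
#' @param object A `pore_stats` object.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pore_stats <- function(object, bins = 30, ...) {
  if (nrow(object$pores) == 0L) {
    stop("no pores to plot (n_pores = 0)", call. = FALSE)
  }
  ggplot2::ggplot(object$pores, ggplot2::aes(.data$ecd_um)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$summary$mean_ecd_um,
                        linetype = "dashed") +
    ggplot2::labs(x = "Equivalent Circular Diameter (um)", y = "pores",
                  title = sprintf("mean ECD %.1f um (n = %d)",
                                  object$summary$mean_ecd_um,
                                  object$summary$n_pores)) +
    ggplot2::theme_minimal()
}

#' Plot a cross-geometry comparison
#'
#' Mean +/- SD of porosity and ECD per geometry, side by side.
#'
#' @param comparison A [compare_geometries()] tibble.
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison) {
  long <- dplyr::bind_rows(
    tibble::tibble(geometry = comparison$geometry, metric = "porosity",
                   mean = comparison$mean_porosity,
                   sd = comparison$sd_porosity),
    tibble::tibble(geometry = comparison$geometry, metric = "ECD (um)",
                   mean = comparison$mean_ecd_um,
                   sd = comparison$sd_ecd_um)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$geometry, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
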