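# Plotting helpers (ggplot2).

#' Plot a synthetic comet field
#'
#' Intensity raster (log scale) with the registered lattice overlaid when a
#' grid fit is supplied.
#'
#' @param field A `comet_field`.
#' @param grid Optional [register_grid()] fit to overlay.
#' @param downsample Integer pixel stride for plotting speed.
#' @return A ggplot object.
#' @export
plot_field <- function(field, grid = NULL, downsample = 2L) {
  img <- field$intensity
  ys <- seq(1, nrow(img), by = downsample)
  xs <- seq(1, ncol(img), by = downsample)
  d <- tidyr::expand_grid(y = ys, x = xs) %>%
    mutate(intensity = img[cbind(.data$y, .data$x)])
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log1p(.data$intensity))) +
    ggplot2::scale_fill_viridis_c(name = "log(1+I)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(grid)) {
    p <- p + ggplot2::geom_point(data = grid$nodes, shape = 3,
                                 colour = "red", size = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gamma standard curve
#'
#' Measured tail rise against induced SSBs with the fitted line; saturated
#' (excluded) points are hollow.
#'
#' @param object A `comet_standard_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comet_standard_curve <- function(object, ...) {
  d <- object$data %>% filter(.data$dose_gy > 0)
  sl <- object$slope_ssb_per_pct
  ggplot2::ggplot(d, ggplot2::aes(.data$ssb_induced, .data$delta_pct)) +
    ggplot2::geom_abline(slope = 1 / sl,
                         intercept = -object$intercept / sl,
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$saturated), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "saturated") +
    ggplot2::labs(x = "induced SSBs per cell",
                  y = "percent tail DNA above baseline",
                  title = sprintf("%.0f SSB per %%T", sl)) +
    ggplot2::theme_minimal()
}

#' Dose-response plot for a simulated screen
#'
#' Mean percent tail DNA (with SEM bars across wells) by dose, one panel per
#' chemical, coloured by inhibitor arm.
#'
#' @param screen A `comet_screen` from [simulate_screen()].
#' @return A ggplot object.
#' @export
plot_screen_dose_response <- function(screen) {
  stopifnot(inherits(screen, "comet_screen"))
  d <- screen$conditions %>%
    mutate(arm = ifelse(.data$hu_arac, "+HU/AraC", "no inhibitor"))
  ggplot2::ggplot(d, ggplot2::aes(.data$dose, .data$mean_pct,
                                  colour = .data$arm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$sem,
                                        ymax = .data$mean_pct + .data$sem),
                           width = 0) +
    ggplot2::facet_wrap(~chemical, scales = "free_x") +
    ggplot2::labs(x = "dose (native unit)", y = "percent tail DNA",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
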