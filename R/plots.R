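#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

slice_tibble <- function(arr3, slice, spacing) {
  nx <- dim(arr3)[1]; ny <- dim(arr3)[2]
  tibble::tibble(
    x = rep((seq_len(nx) - (nx + 1) / 2) * spacing[1], times = ny),
    y = rep((seq_len(ny) - (ny + 1) / 2) * spacing[2], each = nx),
    value = as.vector(arr3[, , slice]))
}

#' Plot a physical parameter map
#'
#' Raster map of one channel on one z-slice, in physical coordinates.
#'
#' @param object A [coefficients_to_physical()] result (or an `lcfr_fit`).
#' @param channel Channel name (default `"speed"`).
#' @param slice z-slice (default: middle).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.physical_maps <- function(object, channel = "speed", slice = NULL,
                                   ...) {
  stopifnot(channel %in% names(object$maps))
  m <- object$maps[[channel]]
  m[!object$valid] <- NA
  if (is.null(slice)) slice <- (dim(m)[3] + 1L) %/% 2L
  df <- slice_tibble(m, slice, object$spacing)
  lab <- if (nzchar(object$units[channel]))
    sprintf("%s (%s)", channel, object$units[channel]) else channel
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = lab)
}

#' @export
autoplot.lcfr_fit <- function(object, ...) autoplot(object$physical, ...)

#' Quiver plot of the recovered in-plane velocity field
#'
#' @param pm A [coefficients_to_physical()] result.
#' @param slice z-slice (default: middle).
#' @param stride Arrow subsampling stride in voxels.
#' @param scale Arrow length per mm/s, in mm.
#' @return A ggplot object.
#' @export
plot_velocity_field <- function(pm, slice = NULL, stride = 4L, scale = 2) {
  stopifnot(all(c("u_x", "u_y") %in% names(pm$maps)))
  if (is.null(slice)) slice <- (dim(pm$valid)[3] + 1L) %/% 2L
  ux <- pm$maps$u_x; uy <- pm$maps$u_y
  ux[!pm$valid] <- NA; uy[!pm$valid] <- NA
  dfx <- slice_tibble(ux, slice, pm$spacing)
  dfy <- slice_tibble(uy, slice, pm$spacing)
  df <- dplyr::mutate(dfx, uy = dfy$value)
  names(df)[names(df) == "value"] <- "ux"
  df <- df[!is.na(df$ux) &
             (round(df$x / pm$spacing[1]) %% stride == 0) &
             (round(df$y / pm$spacing[2]) %% stride == 0), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + scale * .data$ux,
                                       yend = .data$y + scale * .data$uy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
                          linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Error-vs-noise convergence plot
#'
#' Median relative parameter error against noise level on log axes, one line
#' per scenario/parameter, as produced by [run_validation_suite()].
#'
#' @param report An `experiment_report`.
#' @param parameters Channels to include (default: velocity magnitude and,
#'   when present, Ktrans).
#' @return A ggplot object.
#' @export
plot_convergence <- function(report, parameters = c("speed", "ktrans")) {
  df <- dplyr::filter(report$convergence,
                      .data$parameter %in% parameters,
                      !is.na(.data$median_rel_err))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$noise, y = .data$median_rel_err,
                                   colour = .data$scenario,
                                   linetype = .data$parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "noise level (fraction of max signal)",
                  y = "median relative error (%)")
}

#' @export
autoplot.experiment_report <- function(object, ...) plot_convergence(object, ...)
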