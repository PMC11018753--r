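# ggplot2 methods for the main result types

#' @export
autoplot.tof_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time * 1e9, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "pump-probe delay (ns)", y = "reflectivity (a.u.)")
}

#' @export
autoplot.trbs_spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    f = object$frequency,
    z = object$depth
  )
  df$magnitude <- as.vector(object$coefficients)
  df <- df[rep(object$valid, times = length(object$frequency)), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$z * 1e6, .data$f / 1e9,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "depth (µm)", y = "frequency (GHz)",
                  fill = "|C|")
}

#' @export
autoplot.depth_profile <- function(object, ...) {
  df <- object[object$valid, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$z * 1e6, .data$delta_f / 1e6)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (µm)", y = expression(Delta * f[B] ~ "(MHz)"))
}

#' @export
autoplot.layer_fit <- function(object, ...) {
  df <- attr(object, "fitted")
  ggplot2::ggplot(df, ggplot2::aes(.data$z * 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y / 1e6), size = 0.6,
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit / 1e6), colour = "red") +
    ggplot2::labs(x = "depth (µm)", y = expression(Delta * f[B] ~ "(MHz)"))
}

#' Cross-section image of a scan volume
#'
#' Plots an x-z (or y-z) slice of the relative-shift volume.
#'
#' @param volume A `scan_volume`.
#' @param plane `"xz"` or `"yz"`.
#' @param row Index of the fixed lateral row (iy for `"xz"`, ix for
#'   `"yz"`).
#' @return A ggplot object.
#' @export
plot_cross_section <- function(volume, plane = c("xz", "yz"), row = 1) {
  plane <- match.arg(plane)
  v <- volume$voxels
  if (plane == "xz") {
    v <- v[v$iy == row, ]
    lat <- v$ix
    lab <- "x (pixel)"
  } else {
    v <- v[v$ix == row, ]
    lat <- v$iy
    lab <- "y (pixel)"
  }
  v$lat <- lat
  v <- v[v$valid, ]
  ggplot2::ggplot(v, ggplot2::aes(.data$lat, .data$z * 1e6,
                                  fill = .data$delta_f / 1e6)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = lab, y = "depth (µm)",
                  fill = expression(Delta * f[B] ~ "(MHz)"))
}

#' @export
autoplot.scan_volume <- function(object, ...) {
  plot_cross_section(object, "xz", row = max(1L, object$ny %/% 2L))
}
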