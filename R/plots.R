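#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   scale_fill_viridis_c scale_x_log10 scale_y_log10 labs theme_minimal
#'   coord_equal geom_col
NULL

#' Plot a force-distance curve
#'
#' Force against tip-sample separation, with the separation axis reversed
#' for approach curves so contact reads left-to-right.
#'
#' @param object an [fd_curve()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.fd_curve <- function(object, ...) {
  p <- ggplot(as_tibble(object), aes(.data$separation_nm, .data$force_nN)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Separation (nm)", y = "Force (nN)") +
    theme_minimal()
  if (curve_direction(object) == "approach") {
    p <- p + ggplot2::scale_x_reverse()
  }
  p
}

#' Plot a height map
#' @param object a [height_map()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.height_map <- function(object, ...) {
  px <- pixel_size(object)
  df <- tibble(
    x_nm = (as.vector(col(object)) - 0.5) * px,
    y_nm = (as.vector(row(object)) - 0.5) * px,
    height_nm = as.vector(unclass(object)))
  ggplot(df, aes(.data$x_nm, .data$y_nm, fill = .data$height_nm)) +
    geom_raster() +
    scale_fill_viridis_c(name = "Height (nm)") +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = "x (nm)", y = "y (nm)") +
    theme_minimal()
}

#' Plot the rupture force-thickness map of an analysed batch
#'
#' The 2D scatter of rupture force against rupture thickness, coloured by
#' population label - the event-population map used to distinguish the
#' alpha, beta and gamma rupture classes.
#'
#' @param object an `fs_batch` from [analyze_curves()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.fs_batch <- function(object, ...) {
  ev <- object$events
  if (nrow(ev) == 0) abort("no events to plot")
  map_col <- if ("label" %in% names(ev)) aes(colour = .data$label) else NULL
  ggplot(ev, aes(.data$thickness_nm, .data$rupture_force_nN)) +
    geom_point(map_col, alpha = 0.6, size = 0.9) +
    labs(x = "Rupture thickness (nm)", y = "Rupture force (nN)",
         colour = "Population") +
    theme_minimal()
}

#' Plot a correlogram
#' @param object a [correlogram()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.correlogram <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$lag_s, .data$g2)) +
    geom_point(size = 0.7) +
    scale_x_log10() +
    labs(x = "Lag time (s)", y = "g2") +
    theme_minimal()
}

#' Plot a size distribution
#' @param object a [size_distribution()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$diameter_nm, .data$weight)) +
    geom_col(width = 0.05) +
    scale_x_log10() +
    labs(x = "Diameter (nm)", y = "Intensity weight") +
    theme_minimal()
}

#' Plot a texture spectrum
#' @param object a `texture_spectrum` from [stripe_period()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.texture_spectrum <- function(object, ...) {
  ggplot(object$spectrum, aes(.data$wavelength_nm, .data$power)) +
    geom_line() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "Wavelength (nm)", y = "Spectral power") +
    theme_minimal()
}

#' Plot the MEM fit: data against the modelled correlogram
#' @param object a `mem_fit` from [invert_mem()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.mem_fit <- function(object, ...) {
  df <- bind_rows(
    mutate(as_tibble(object$observed), which = "observed"),
    mutate(as_tibble(object$fitted), which = "fitted"))
  ggplot(df, aes(.data$lag_s, .data$g2, colour = .data$which)) +
    geom_line() +
    scale_x_log10() +
    labs(x = "Lag time (s)", y = "g2", colour = NULL) +
    theme_minimal()
}
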