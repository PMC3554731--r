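#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the optimization trace of a segmentation
#'
#' @param x A `nuclei_segmentation`.
#' @param ... Unused.
#' @return Tibble with `iteration` (0 = initialization) and `energy`.
#' @method tidy nuclei_segmentation
#' @export
tidy.nuclei_segmentation <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$energy_trace) - 1L,
                 energy = x$energy_trace)
}

#' One-row summary of a segmentation
#'
#' @param x A `nuclei_segmentation`.
#' @param ... Unused.
#' @return Tibble with grid size, iteration count, initial/final energy,
#'   convergence flag and the foreground area of the thresholded labeling.
#' @method glance nuclei_segmentation
#' @export
glance.nuclei_segmentation <- function(x, ...) {
  n_it <- max(length(x$energy_trace) - 1L, 0L)
  tibble::tibble(
    height = nrow(x$u), width = ncol(x$u),
    n_radii = length(x$dict$radii),
    outer_iterations = n_it,
    energy_initial = if (length(x$energy_trace)) x$energy_trace[1L] else NA_real_,
    energy_final = if (length(x$energy_trace)) x$energy_trace[length(x$energy_trace)] else NA_real_,
    converged = x$converged,
    foreground_px = sum(threshold_u(x$u, x$params$u_threshold)))
}

field_to_df <- function(m, value_name = "value") {
  df <- expand.grid(y_px = seq_len(nrow(m)) - 1L, x_px = seq_len(ncol(m)) - 1L)
  df[[value_name]] <- as.vector(m)
  tibble::as_tibble(df)
}

#' Plot a segmentation result
#'
#' Raster of the relaxed labeling `u` (or the merged coefficient map) in
#' image orientation.
#'
#' @param object A `nuclei_segmentation`.
#' @param field `"u"` (default) or `"t_merged"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nuclei_segmentation
#' @export
autoplot.nuclei_segmentation <- function(object, field = c("u", "t_merged"),
                                         ...) {
  field <- match.arg(field)
  m <- if (field == "u") object$u else merge_coefficients(object$t)
  df <- field_to_df(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_px, y = .data$y_px,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = field) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot detections over an image
#'
#' @param image Intensity matrix (e.g. the preprocessed image).
#' @param detections Detection tibble from [detect()].
#' @param truth Optional ground-truth centroid table (`x_px`, `y_px`).
#' @return A ggplot object: grayscale image, detection circles, optional
#'   truth crosses.
#' @export
plot_detections <- function(image, detections, truth = NULL) {
  df <- field_to_df(image, "intensity")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x_px, y = .data$y_px)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (nrow(detections) > 0) {
    circ <- do.call(rbind, lapply(seq_len(nrow(detections)), function(i) {
      th <- seq(0, 2 * pi, length.out = 60)
      data.frame(id = i,
                 x = detections$x_px[i] + detections$radius_px[i] * cos(th),
                 y = detections$y_px[i] + detections$radius_px[i] * sin(th))
    }))
    p <- p + ggplot2::geom_path(data = circ,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             group = .data$id),
                                color = "cyan", linewidth = 0.4)
  }
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + ggplot2::geom_point(data = as.data.frame(truth),
                                 ggplot2::aes(x = .data$x_px, y = .data$y_px),
                                 color = "red", shape = 3, size = 1.5)
  }
  p
}

#' @importFrom rlang .data
NULL
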