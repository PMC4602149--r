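# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PSTH
#'
#' @param object A `psth`.
#' @param smooth Overlay the 25 ms-smoothed rate.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psth <- function(object, smooth = TRUE, ...) {
  df <- tibble::tibble(time = object$time, rate = object$rate,
                       smoothed = smooth_psth_rate(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey70") +
    ggplot2::labs(x = "time from stimulus onset (s)", y = "firing rate (Hz)")
  if (smooth) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                                colour = "firebrick")
  }
  p
}

#' Plot an amplitude map as an electrode heat map
#'
#' @param object An [amplitude_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.amplitude_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$amplitude)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "peak-to-peak (uV)") +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Plot the silhouette profile of a k-means sweep
#'
#' @param object An `rgc_clusters` model.
#' @param ... Unused.
#' @return A ggplot of mean silhouette against k, with the selected k marked.
#' @export
autoplot.rgc_clusters <- function(object, ...) {
  ggplot2::ggplot(object$per_k,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "k", y = "mean silhouette")
}

#' Plot a pairwise separation matrix
#'
#' @param separation Matrix from [separation_matrix()].
#' @return A ggplot tile map of the pairwise separation coefficients.
#' @export
plot_separation <- function(separation) {
  df <- tibble::as_tibble(as.table(separation), .name_repair = "minimal")
  names(df) <- c("cluster_a", "cluster_b", "separation")
  df <- df[df$cluster_a != df$cluster_b, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster_a, y = .data$cluster_b,
                                   fill = .data$separation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$separation)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c(name = "separation") +
    ggplot2::labs(x = "cluster", y = "cluster")
}

#' Plot a DS polar summary
#'
#' @param object A [ds_polar_summary()].
#' @param ... Unused.
#' @return A polar ggplot of the direction density with modes marked.
#' @export
autoplot.ds_polar_summary <- function(object, ...) {
  ggplot2::ggplot(object$density,
                  ggplot2::aes(x = .data$direction_deg, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mode_directions,
                        colour = "firebrick", linetype = "dotted") +
    ggplot2::coord_polar() +
    ggplot2::labs(x = "preferred direction (deg)", y = "density")
}

#' @importFrom rlang .data
NULL
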