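#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_point geom_tile
#'   geom_hline facet_wrap coord_polar labs theme_minimal autoplot
#'   scale_fill_viridis_c scale_y_continuous
NULL

#' Plot direction tuning curves
#'
#' Polar plot of the occurrence-normalised tuning curve per filter
#' (0 degrees = upward motion, 90 = rightward).
#'
#' @param object A `tuning_curves` object.
#' @param filters Optional subset of filters to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot tuning_curves
autoplot.tuning_curves <- function(object, filters = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(filters)) df <- df[df$filter %in% filters, ]
  ggplot(df, aes(x = .data$angle, y = .data$theta_f)) +
    geom_line(colour = "steelblue") +
    coord_polar(start = pi, direction = -1) +
    facet_wrap(~filter) +
    labs(x = "ball direction (deg, 0 = up, 90 = right)",
         y = expression(theta[f])) +
    theme_minimal()
}

#' Plot the visibility sweep
#'
#' Mean absolute end-point error against the visible fraction of the
#' trajectory, with the naive training-mean baseline as a dashed line.
#'
#' @param object A `visibility_eval` from [evaluate_visibility()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot visibility_eval
autoplot.visibility_eval <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$percentage, y = .data$mean_ae)) +
    geom_line(colour = "steelblue") +
    geom_point(colour = "steelblue") +
    geom_hline(aes(yintercept = .data$baseline_ae), linetype = "dashed") +
    scale_y_continuous(limits = c(0, NA)) +
    labs(x = "visibility (% of trajectory duration)",
         y = "mean absolute error (px)") +
    theme_minimal()
}

#' Plot learned kernels of one layer
#'
#' Raster of the 5 x 5 kernel weights per filter and input channel. For
#' layer 1 the six channels are ON/OFF crossed with the three delay lines.
#'
#' @param network An `snn_network`.
#' @param layer Layer index.
#' @param filters Optional subset of filters.
#' @return A ggplot.
#' @export
plot_kernels <- function(network, layer = 1, filters = NULL) {
  w <- network$layers[[layer]]$weights
  dn <- dim(w)
  df <- expand.grid(filter = seq_len(dn[1]), dy = seq_len(dn[2]) - 1,
                    dx = seq_len(dn[3]) - 1, channel = seq_len(dn[4]) - 1)
  df$weight <- as.numeric(w)
  if (!is.null(filters)) df <- df[df$filter %in% filters, ]
  ggplot(df, aes(x = .data$dx, y = -.data$dy, fill = .data$weight)) +
    geom_tile() +
    facet_wrap(filter ~ channel,
               labeller = ggplot2::label_both, ncol = dn[4]) +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a score state
#'
#' @param object A `score_state`.
#' @param ... Unused.
#' @return A ggplot of score against candidate reception height.
#' @export
#' @method autoplot score_state
autoplot.score_state <- function(object, ...) {
  df <- tibble(y = object$y_grid, score = object$score)
  ggplot(df, aes(x = .data$y, y = .data$score)) +
    geom_line(colour = "steelblue") +
    labs(x = "candidate reception height (px)", y = "score") +
    theme_minimal()
}

#' Plot spike positions coloured by filter
#'
#' Spatial spike map of selected filters over the ball path, the raw
#' material of the unsupervised tracking analysis.
#'
#' @param spikes Spike tibble (`filter`, `x`, `y`).
#' @param filters Optional subset of filters.
#' @return A ggplot.
#' @export
plot_spike_positions <- function(spikes, filters = NULL) {
  df <- as_tibble(spikes)
  if (!is.null(filters)) df <- df[df$filter %in% filters, ]
  ggplot(df, aes(x = .data$x, y = -.data$y,
                 colour = factor(.data$filter))) +
    geom_point(alpha = 0.5, size = 0.8) +
    labs(x = "x (map px)", y = "y (map px, up)", colour = "filter") +
    theme_minimal()
}
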