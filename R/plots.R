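# ggplot2 views of the main result types.

scene_palette <- c("1_UnCon Sub" = "#d8b365", "2_MA" = "#1b512d",
                   "3_SG" = "#5ab46d", "ReefStructure" = "#7f7f88")

#' Plot a synthetic scene with its grid annotation
#'
#' Renders the (downsampled) image with the 64 grid points coloured by their
#' ground-truth class.
#'
#' @param object A [generate_scene()] result.
#' @param max_width Downsample the raster to at most this many columns.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synthetic_scene <- function(object, max_width = 480, ...) {
  px <- object$image$pixels
  W <- dim(px)[2]; H <- dim(px)[1]
  sc <- min(1, max_width / W)
  small <- resize_image(px, max(1, round(W * sc)), max(1, round(H * sc)))
  d <- dim(small)
  df <- tidyr::expand_grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$fill <- grDevices::rgb(small[, , 1][cbind(df$y, df$x)] / 255,
                            small[, , 2][cbind(df$y, df$x)] / 255,
                            small[, , 3][cbind(df$y, df$x)] / 255)
  ann <- object$annotation
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df, ggplot2::aes(x = .data$x, y = .data$y),
                         fill = df$fill) +
    ggplot2::geom_point(data = ann,
                        ggplot2::aes(x = (.data$x + 0.5) * sc,
                                     y = (.data$y + 0.5) * sc,
                                     colour = .data$label),
                        size = 2, shape = 21, stroke = 1.2, fill = "white") +
    ggplot2::scale_colour_manual(values = scene_palette) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = object$image$image_id, colour = "class",
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a confusion matrix
#'
#' @param object A [confusion()] matrix.
#' @param ... Unused.
#' @return A ggplot tile map with counts.
#' @export
autoplot.conf_mat <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

loss_trace_plot <- function(trace, title) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$epoch, y = .data$loss))
  if ("stage" %in% names(trace)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = factor(.data$stage))) +
      ggplot2::labs(colour = "stage")
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(title = title, x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Plot training loss traces
#'
#' @param object A trained `grid_model` or `patch_model`.
#' @param ... Unused.
#' @return A ggplot of loss per epoch (per stage for the patch model).
#' @export
autoplot.grid_model <- function(object, ...) {
  loss_trace_plot(object$loss_trace, "grid model: head training loss")
}

#' @rdname autoplot.grid_model
#' @export
autoplot.patch_model <- function(object, ...) {
  loss_trace_plot(object$loss_trace, "patch model: head training loss")
}

#' Plot per-class precision and recall
#'
#' @param object A [metrics_report()] or [presence_metrics()].
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class, c("precision", "recall"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.metrics_report
#' @export
autoplot.presence_metrics <- autoplot.metrics_report
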