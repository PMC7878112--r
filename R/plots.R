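#' Plot a covariance map as a heat tile
#'
#' @param object A `covariance_map`.
#' @param ... Unused.
#' @return A ggplot object (row index increasing downward, matching the
#'   rendered raster orientation).
#' @export
autoplot.covariance_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))[(df$col - 1) * nrow(object) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "cov") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = attr(object, "mode_cov") %||% "col",
                  y = attr(object, "mode_cov") %||% "row") +
    ggplot2::theme_minimal()
}

#' Plot a rendered contour image
#'
#' @param object A `contour_image`.
#' @param ... Unused.
#' @return A ggplot object showing the raster at its native pixels.
#' @export
autoplot.contour_image <- function(object, ...) {
  d <- dim(object)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  ix <- (df$col - 1) * d[1] + df$row
  a <- unclass(object)
  df$fill <- grDevices::rgb(a[, , 1][ix], a[, , 2][ix], a[, , 3][ix],
                            maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot training curves of a fitted network
#'
#' Accuracy and loss per epoch for the training and (when present)
#' validation sets.
#'
#' @param object A `cnn_fit` from [train_cnn()].
#' @param ... Unused.
#' @return A ggplot object faceted into accuracy and loss panels.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  h <- object$epoch_history
  long <- tidyr::pivot_longer(
    h, dplyr::any_of(c("train_loss", "train_accuracy",
                       "val_loss", "val_accuracy")),
    names_to = c("set", "measure"), names_sep = "_"
  )
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a degradation table
#'
#' Selected metrics against the missingness rate.
#'
#' @param object A `degradation_table` from [degradation_experiment()].
#' @param metrics Character vector of metric names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.degradation_table <- function(object,
                                       metrics = c("accuracy", "precision",
                                                   "informedness"), ...) {
  df <- object[object$metric %in% metrics, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "missing-entry fraction", y = "metric value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a signal recording
#'
#' One facet per channel, amplitude against time; labeled activity
#' intervals are shaded.
#'
#' @param object A [recording()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wearable_recording <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value))
  if (nrow(object$labels) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$labels,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$activity),
      alpha = 0.15, inherit.aes = FALSE
    )
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
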