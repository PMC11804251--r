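# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an axial slice of a volume
#'
#' @param vol a [volume()] or 3D array.
#' @param z 0-based slice index (default: middle slice).
#' @param centroids optional [centroid_set()] / [particle_set()] whose points
#'   within one voxel of the slice are overlaid.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, z = NULL, centroids = NULL) {
  m <- vol_data(vol)
  if (is.null(z)) z <- (dim(m)[1] - 1) %/% 2
  sl <- m[z + 1, , ]
  df <- expand.grid(y = seq_len(nrow(sl)) - 1, x = seq_len(ncol(sl)) - 1)
  df$value <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice z = %d", z), fill = "intensity")
  if (!is.null(centroids) && nrow(centroids) > 0) {
    near <- abs(centroids$z - z) <= 1
    if (any(near)) {
      p <- p + ggplot2::geom_point(
        data = data.frame(x = centroids$x[near], y = centroids$y[near]),
        ggplot2::aes(x = .data$x, y = .data$y), inherit.aes = FALSE,
        colour = "red", shape = 1, size = 3)
    }
  }
  p
}

#' Plot training curves
#'
#' @param object a `tomo_fit`.
#' @param ... unused.
#' @return A ggplot of train/validation loss per epoch, with the best epoch
#'   marked.
#' @export
autoplot.tomo_fit <- function(object, ...) {
  log <- tidy(object)
  df <- tidyr_pivot(log)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "composite loss", colour = NULL)
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(log) {
  rbind(data.frame(epoch = log$epoch, loss = log$train_loss, split = "train"),
        data.frame(epoch = log$epoch, loss = log$val_loss, split = "validation"))
}

#' Plot a confidence-percentile sweep
#'
#' @param object a `sweep_table` from [threshold_sweep()].
#' @param ... unused.
#' @return A ggplot of precision, recall and F1 against the swept percentile,
#'   with the F1-maximal percentile marked.
#' @export
autoplot.sweep_table <- function(object, ...) {
  df <- rbind(
    data.frame(percentile = object$percentile, value = object$precision,
               metric = "precision"),
    data.frame(percentile = object$percentile, value = object$recall,
               metric = "recall"),
    data.frame(percentile = object$percentile, value = object$f1,
               metric = "F1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percentile, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$percentile[object$is_best],
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "confidence percentile", y = NULL, colour = NULL)
}
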