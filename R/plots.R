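#' @import ggplot2
#' @importFrom rlang .data
NULL

#' Plot a 2-D feature space coloured by group
#'
#' Scatter plot of the first two embedding scores with per-group centroids
#' overlaid as crosses.
#'
#' @param object A `feature_space` tibble from [embed_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot feature_space
#' @export
autoplot.feature_space <- function(object, ...) {
  cent <- attr(object, "centroids") %||% group_centroids(object)
  ggplot(object, aes(.data$score_1, .data$score_2, colour = .data$group)) +
    geom_point(alpha = 0.7, size = 1.6) +
    geom_point(data = cent, shape = 4, size = 3, stroke = 1.2,
               show.legend = FALSE) +
    labs(x = "score 1", y = "score 2", colour = "group",
         title = "Trained feature space") +
    theme_minimal()
}

#' Plot the training log of a contrast network
#'
#' Per-batch contrastive loss (log scale) across rounds, with the
#' end-of-round nearest-centroid training error overlaid.
#'
#' @param object A [train_contrast_cnn()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contrast_cnn
#' @export
autoplot.contrast_cnn <- function(object, ...) {
  log <- object$log
  log$step <- seq_len(nrow(log))
  err <- log[!is.na(log$train_error), ]
  ggplot(log, aes(.data$step, .data$loss)) +
    geom_line(colour = "grey40", linewidth = 0.3) +
    geom_point(data = err, aes(y = .data$train_error), colour = "firebrick",
               size = 2) +
    scale_y_log10() +
    labs(x = "batch", y = "loss (log scale), training error (points)",
         title = "Contrastive training log") +
    theme_minimal()
}

#' Plot a t-SNE ordination grid
#'
#' One panel per (perplexity, iterations) grid cell, points coloured by
#' group when group labels are available.
#'
#' @param object A [tsne_ordination()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tsne_ordination
#' @export
autoplot.tsne_ordination <- function(object, ...) {
  p <- ggplot(object, aes(.data$dim_1, .data$dim_2)) +
    facet_grid(iterations ~ perplexity, labeller = label_both,
               scales = "free") +
    labs(x = "t-SNE 1", y = "t-SNE 2", title = "t-SNE ordination grid") +
    theme_minimal()
  if ("group" %in% names(object)) {
    p + geom_point(aes(colour = .data$group), size = 1, alpha = 0.7)
  } else {
    p + geom_point(size = 1, alpha = 0.7)
  }
}

#' Render a specimen image or difference image with ggplot2
#'
#' @param img Numeric matrix (pixel values in \[0, 1\] or \[0, 255\]).
#' @param title Optional plot title.
#' @return A ggplot object drawn in grayscale.
#' @export
plot_image <- function(img, title = NULL) {
  img <- to_unit_range(as_pixel_matrix(img))
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  ggplot(df, aes(.data$col, .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    scale_y_reverse() +
    coord_fixed() +
    labs(title = title) +
    theme_void() +
    theme(legend.position = "none")
}
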