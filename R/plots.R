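# ggplot2 front-ends for the result objects.

#' Plot a training trajectory
#'
#' @param object An `hrcc_fit`.
#' @param ... Unused.
#' @return A ggplot with loss curves and validation mean AUC per epoch.
#' @export
autoplot.hrcc_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot ROC curves of an evaluation report
#'
#' @param object An `hrcc_metrics_report`.
#' @param ... Unused.
#' @return A ggplot with one ROC curve per class and the chance
#'   diagonal.
#' @export
autoplot.hrcc_metrics_report <- function(object, ...) {
  dfs <- purrr::imap(object$roc, function(r, nm) {
    if (is.null(r)) return(NULL)
    dplyr::mutate(r$points, class = nm)
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL,
                  subtitle = sprintf("mean AUC = %.3f", object$mean_auc)) +
    ggplot2::theme_minimal()
}

#' Plot an activation heatmap over its image
#'
#' @param heatmap An `(h, w)` matrix in `[0, 1]` from
#'   [activation_heatmap()].
#' @param image Optional underlying grayscale image for the overlay.
#' @param alpha Overlay opacity.
#' @return A ggplot raster plot.
#' @export
plot_heatmap <- function(heatmap, image = NULL, alpha = 0.6) {
  d <- dim(heatmap)
  df <- tidyr::expand_grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$value <- as.vector(heatmap)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(image)) {
    di <- tidyr::expand_grid(y = seq_len(nrow(image)), x = seq_len(ncol(image)))
    di$gray <- as.vector(image)
    p <- p + ggplot2::geom_raster(data = di,
                                  ggplot2::aes(fill = NULL, alpha = NULL),
                                  fill = grDevices::gray(di$gray))
  }
  p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value), alpha = alpha) +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "activation") +
    ggplot2::theme_void()
}

#' Write a heatmap overlay PNG
#'
#' @param heatmap `(h, w)` matrix in `[0, 1]`.
#' @param path Output PNG path.
#' @param image Optional grayscale image blended under the heatmap.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heatmap, path, image = NULL) {
  h <- dim(heatmap)[1]; w <- dim(heatmap)[2]
  # simple inferno-like ramp: black -> red -> yellow -> white
  r <- pmin(1, heatmap * 3)
  g <- pmin(1, pmax(0, heatmap * 3 - 1))
  b <- pmin(1, pmax(0, heatmap * 3 - 2))
  rgb <- array(c(r, g, b), c(h, w, 3))
  if (!is.null(image)) {
    base <- array(rep(image, 3), c(h, w, 3))
    rgb <- 0.4 * base + 0.6 * rgb
  }
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
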