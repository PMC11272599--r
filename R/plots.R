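#' Plot an ECG fragment
#'
#' @param fragment One row of a fragment tibble (or a fragment tibble; the
#'   first row is used).
#' @return A ggplot of voltage against time.
#' @export
plot_fragment <- function(fragment) {
  check_fragments(fragment)
  x <- fragment[1, ]
  d <- tibble::tibble(time_s = (seq_along(x$samples[[1]]) - 1) / x$fs,
                      mV = x$samples[[1]])
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(title = paste0(x$id, " (", x$label, ")"),
                  x = "time (s)", y = "mV") +
    ggplot2::theme_minimal()
}

#' Plot a scalogram image
#'
#' @param img A `scalogram_image` (8-bit H x W x 3 array).
#' @return A ggplot raster of the image.
#' @export
plot_scalogram <- function(img) {
  d <- dim(img)
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(img[, , 1] / 255, img[, , 2] / 255,
                            img[, , 3] / 255)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "time", y = "scale (high frequency at top)") +
    ggplot2::theme_void()
}

#' @rdname plot_training_history
#' @export
autoplot.shock_fit <- function(object, ...) {
  plot_training_history(object)
}

#' Training and validation curves of a fit
#'
#' @param object,fit A `shock_fit`.
#' @param ... Unused.
#' @return A ggplot of accuracy and loss per epoch, faceted by metric.
#' @export
plot_training_history <- function(fit) {
  h <- tidyr::pivot_longer(fit$history, -"epoch",
                           names_to = c("set", "metric"),
                           names_sep = "_", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_confusion
#' @export
autoplot.shock_eval <- function(object, type = c("confusion", "roc"), ...) {
  type <- match.arg(type)
  if (type == "confusion") plot_confusion(object) else plot_roc(object)
}

#' Confusion-matrix heatmap of an evaluation report
#'
#' @param object,report A `shock_eval`.
#' @param ... Unused.
#' @return A ggplot heatmap (rows = true class, columns = predicted).
#' @export
plot_confusion <- function(report) {
  cm <- as.data.frame(as.table(report$confusion))
  names(cm) <- c("true", "predicted", "n")
  ggplot2::ggplot(cm, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves of an evaluation report
#'
#' @param report A `shock_eval`.
#' @return A ggplot of the per-class ROC curves with AUC in the legend.
#' @export
plot_roc <- function(report) {
  roc <- report$roc
  lab <- sprintf("%s (AUC %.3f)", names(report$auc), report$auc)
  roc$class <- factor(roc$class, levels = names(report$auc), labels = lab)
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr,
                                    colour = .data$class)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Overlay the most influential superpixels on a scalogram
#'
#' @param explanation A `shock_explanation`.
#' @param image The explained 8-bit image.
#' @param k Number of top superpixels to highlight.
#' @return A ggplot of the image with the top-k superpixels outlined.
#' @export
plot_explanation <- function(explanation, image, k = 5) {
  p <- plot_scalogram(image)
  map <- attr(explanation, "map")
  top <- top_superpixels(explanation, k)
  cells <- purrr::map(top$superpixel, function(sp) {
    hit <- which(unclass(map) == sp, arr.ind = TRUE)
    tibble::tibble(xmin = min(hit[, 2]) - 0.5, xmax = max(hit[, 2]) + 0.5,
                   ymin = min(hit[, 1]) - 0.5, ymax = max(hit[, 1]) + 0.5)
  })
  cells <- dplyr::bind_rows(cells)
  p + ggplot2::geom_rect(
    data = cells,
    ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                 ymin = .data$ymin, ymax = .data$ymax),
    inherit.aes = FALSE, fill = NA, colour = "yellow", linewidth = 0.8
  )
}
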