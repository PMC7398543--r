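# ggplot2 visualisation helpers

raster_df <- function(m, value = "value") {
  d <- data.frame(row = rep(seq_len(nrow(m)), times = ncol(m)),
                  col = rep(seq_len(ncol(m)), each = nrow(m)),
                  value = as.vector(m))
  names(d)[3L] <- value
  d
}

#' Plot a slice
#'
#' Intensity raster with row 1 at the top; with `what = "labels"` the four
#' tissue classes are drawn as discrete fills.
#'
#' @param object A [slice_image()].
#' @param what `"intensity"` or `"labels"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slice_image <- function(object, what = c("intensity", "labels"), ...) {
  what <- match.arg(what)
  if (what == "labels") {
    if (is.null(object$labels)) stop_validation("slice has no labels")
    return(plot_label_map(object$labels) +
             ggplot2::ggtitle(sprintf("%s slice %d", object$plane,
                                      object$index)))
  }
  d <- raster_df(object$pixels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity",
                  title = sprintf("%s slice %d", object$plane, object$index)) +
    ggplot2::theme_minimal()
}

#' Plot a label map
#'
#' @param labels Integer label matrix (0 background, 1 CSF, 2 GM, 3 WM).
#' @return A ggplot object.
#' @export
plot_label_map <- function(labels) {
  d <- raster_df(labels, "class")
  cls <- tissue_classes()
  d$class <- factor(d$class, levels = unname(cls), labels = names(cls))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(background = "black",
                                          CSF = "#2166ac", GM = "#999999",
                                          WM = "#f7f7f7"), drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "tissue") +
    ggplot2::theme_minimal()
}

#' Plot a training curve
#'
#' Per-epoch mean loss and mean patch pixel-accuracy from a trained model's
#' history.
#'
#' @param object A trained `unet_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unet_model <- function(object, ...) {
  h <- tidy(object)
  if (nrow(h) == 0L) stop_validation("model has no training history")
  d <- rbind(data.frame(epoch = h$epoch, metric = "loss", value = h$loss),
             data.frame(epoch = h$epoch, metric = "accuracy",
                        value = h$accuracy))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation report
#'
#' Per-class bars of DSC and JI from [evaluate_segmentation()].
#'
#' @param object A `seg_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seg_report <- function(object, ...) {
  p <- object$per_class
  d <- rbind(data.frame(class = p$class, metric = "DSC", value = p$dice),
             data.frame(class = p$class, metric = "JI", value = p$jaccard))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
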