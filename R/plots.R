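# ggplot2 displays for fits and metric reports.

#' Training curves of a fitted model
#'
#' @param object An `hcn_fit`.
#' @param ... Unused.
#' @return A ggplot with loss and accuracy panels over epochs.
#' @export
autoplot.hcn_fit <- function(object, ...) {
  h <- object$history
  long <- rbind(
    data.frame(epoch = h$epoch, value = h$train_loss, series = "train", panel = "loss"),
    data.frame(epoch = h$epoch, value = h$val_loss, series = "validation", panel = "loss"),
    data.frame(epoch = h$epoch, value = h$train_acc, series = "train", panel = "accuracy"),
    data.frame(epoch = h$epoch, value = h$val_acc, series = "validation", panel = "accuracy"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of a metric report
#'
#' @param object An `hcn_metric_report`.
#' @param ... Unused.
#' @export
autoplot.hcn_metric_report <- function(object, ...) {
  cm <- object$confusion
  df <- as.data.frame(as.table(cm))
  names(df) <- c("truth", "prediction", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("accuracy %.3f", object$accuracy)) +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves
#'
#' @param probabilities `N x K` probability matrix.
#' @param labels True labels (see [evaluate()]).
#' @param classes Class names in column order.
#' @return A ggplot of per-class ROC curves with the chance diagonal.
#' @export
plot_roc <- function(probabilities, labels, classes = NULL) {
  K <- ncol(probabilities)
  y <- .as_label_index(labels, K, classes)
  cls <- classes %||% paste0("class", seq_len(K))
  pts <- do.call(rbind, lapply(seq_len(K), function(k) {
    truth <- as.integer(y == k)
    if (!any(truth == 1) || all(truth == 1)) return(NULL)
    ord <- order(probabilities[, k], decreasing = TRUE)
    t <- truth[ord]
    data.frame(fpr = c(0, cumsum(1 - t) / sum(1 - t)),
               tpr = c(0, cumsum(t) / sum(t)),
               class = cls[k])
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL
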