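# Multi-metric evaluation, inference-time ensembling and seed aggregation.
#
# Accuracy is argmax agreement (ties toward the lowest class index);
# "AP" is micro-averaged precision (all one-vs-rest decisions pooled before
# the precision-recall integration) while "precision", "recall" and "F1"
# are macro averages over classes; AUC is reported both micro (pooled) and
# macro (unweighted class mean), with trapezoidal ROC integration.

#' Evaluate class-probability predictions
#'
#' @param probabilities `N x K` matrix; each row a class distribution
#'   (checked to sum to 1 within 1e-5).
#' @param labels Length-`N` true labels: integer class indices (1-based) or
#'   factor/character mapped against `classes`.
#' @param classes Optional class names in column order.
#' @return An `hcn_metric_report`: accuracy, micro-AP, macro precision /
#'   recall / F1, micro and macro AUC, and the K x K confusion matrix
#'   (rows = truth).
#' @export
evaluate <- function(probabilities, labels, classes = NULL) {
  probabilities <- as.matrix(probabilities)
  K <- ncol(probabilities)
  if (any(abs(rowSums(probabilities) - 1) > 1e-5))
    stop("evaluate: probability rows must sum to 1")
  y <- .as_label_index(labels, K, classes)
  n <- length(y)
  if (nrow(probabilities) != n) stop("evaluate: nrow(probabilities) != length(labels)")
  pred <- max.col(probabilities, ties.method = "first")
  dn <- if (!is.null(classes) && length(classes) == K)
    list(truth = classes, prediction = classes) else NULL
  cm <- matrix(0L, K, K, dimnames = dn)
  for (i in seq_len(n)) cm[y[i], pred[i]] <- cm[y[i], pred[i]] + 1L
  acc <- sum(diag(cm)) / n
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    prec[k] <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec[k] <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  present <- which(rowSums(cm) > 0)
  onehot <- matrix(0L, n, K)
  onehot[cbind(seq_len(n), y)] <- 1L
  auc_k <- vapply(present, function(k)
    .roc_auc(probabilities[, k], onehot[, k]), numeric(1))
  structure(list(
    accuracy = acc,
    micro_AP = .average_precision(as.vector(probabilities), as.vector(onehot)),
    precision = mean(prec[present]),
    recall = mean(rec[present]),
    F1 = mean(f1[present]),
    micro_AUC = .roc_auc(as.vector(probabilities), as.vector(onehot)),
    macro_AUC = mean(auc_k),
    confusion = cm,
    n = n, classes = classes),
    class = "hcn_metric_report")
}

.as_label_index <- function(labels, K, classes = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (is.null(classes)) stop("evaluate: character labels need `classes`")
    y <- match(labels, classes)
  } else {
    y <- as.integer(labels)
  }
  if (anyNA(y) || any(y < 1L) || any(y > K))
    stop("evaluate: label outside [1, ", K, "]")
  y
}

# Trapezoidal one-vs-rest ROC AUC over pooled scores.
.roc_auc <- function(scores, truth) {
  pos <- sum(truth == 1); neg <- sum(truth == 0)
  if (pos == 0 || neg == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  # group tied thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t); fp <- cumsum(1 - t)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / pos)
  fpr <- c(0, fp[last] / neg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Step-wise average precision (area under the PR curve, pooled decisions).
.average_precision <- function(scores, truth) {
  pos <- sum(truth == 1)
  if (pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  t <- truth[ord]
  tp <- cumsum(t)
  prec <- tp / seq_along(t)
  rec <- tp / pos
  sum(diff(c(0, rec)) * prec)
}

#' @export
print.hcn_metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric report, n = %d>\n  accuracy %.4f | AP(micro) %.4f | ",
                     "precision %.4f | recall %.4f | F1 %.4f\n",
                     "  AUC micro %.4f | AUC macro %.4f\n"),
              x$n, x$accuracy, x$micro_AP, x$precision, x$recall, x$F1,
              x$micro_AUC, x$macro_AUC))
  invisible(x)
}

#' Tidy a metric report into a one-row-per-metric tibble
#' @param x An `hcn_metric_report`.
#' @param ... Unused.
#' @export
tidy.hcn_metric_report <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "micro_AP", "precision", "recall", "F1",
               "micro_AUC", "macro_AUC"),
    value = c(x$accuracy, x$micro_AP, x$precision, x$recall, x$F1,
              x$micro_AUC, x$macro_AUC))
}

#' @export
glance.hcn_fit <- function(x, ...) {
  tibble::tibble(model = x$model$spec$name, variant = x$model$spec$variant,
                 seed = x$seed, epochs = nrow(x$history),
                 best_epoch = x$best_epoch, best_val_loss = x$best_val_loss,
                 final_train_acc = x$history$train_acc[nrow(x$history)],
                 parameters = count_parameters(x$model))
}

#' @export
tidy.hcn_fit <- function(x, ...) tibble::as_tibble(x$history)

#' Average the predictions of several models (inference-time ensemble)
#'
#' @param prob_sets List of `N x K` probability matrices (same shape).
#' @return Elementwise mean; rows remain distributions.
#' @export
ensemble_predict <- function(prob_sets) {
  if (is.matrix(prob_sets)) prob_sets <- list(prob_sets)
  if (!length(prob_sets)) stop("ensemble_predict: empty input")
  d <- dim(prob_sets[[1]])
  for (p in prob_sets)
    if (!identical(dim(p), d)) stop("ensemble_predict: shape mismatch")
  Reduce(`+`, prob_sets) / length(prob_sets)
}

#' Mean and standard deviation of metrics across seed runs
#'
#' @param reports List of `hcn_metric_report`s (one per seed).
#' @return Tibble with per-metric mean and population-of-seeds SD.
#' @export
aggregate_seeds <- function(reports) {
  if (inherits(reports, "hcn_metric_report")) reports <- list(reports)
  if (!length(reports)) stop("aggregate_seeds: empty report list")
  tidies <- lapply(reports, tidy.hcn_metric_report)
  vals <- sapply(tidies, function(t) t$value)
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
  # population SD across the seed runs (the +/- convention of the result tables)
  sds <- apply(vals, 1, function(v) sqrt(mean((v - mean(v))^2)))
  tibble::tibble(metric = tidies[[1]]$metric,
                 mean = rowMeans(vals), sd = sds, n_seeds = length(reports))
}

#' @importFrom generics tidy glance
NULL
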