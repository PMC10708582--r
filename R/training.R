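# Training protocol: class-weighted categorical cross-entropy, SGD with
# momentum, learning-rate halving on validation plateau, early stopping with
# best-checkpoint restoration, and seeded reproducibility.

#' Inverse-frequency class weights
#'
#' `w_k = N_total / (K * n_k)`: balanced classes get weight 1, rare classes
#' proportionally more, and the weights average to 1 under the class
#' distribution.
#'
#' @param class_counts Named (or unnamed) positive integer vector of
#'   per-class sample counts.
#' @return Numeric vector of weights, same names/order as the input.
#' @export
compute_class_weights <- function(class_counts) {
  counts <- as.numeric(class_counts)
  if (any(counts <= 0)) {
    bad <- names(class_counts)[counts <= 0] %||% which(counts <= 0)
    stop("compute_class_weights: zero count for class ",
         paste(bad, collapse = ", "))
  }
  w <- sum(counts) / (length(counts) * counts)
  names(w) <- names(class_counts)
  w
}

#' Class-weighted categorical cross-entropy of one prediction
#'
#' @param probs Probability vector over classes (must sum to 1 within 1e-5).
#' @param label Class index (1-based) of the true class.
#' @param weights Per-class weights (default all 1).
#' @return `-weights[label] * log(probs[label])`.
#' @export
weighted_cross_entropy <- function(probs, label, weights = rep(1, length(probs))) {
  if (abs(sum(probs) - 1) > 1e-5)
    stop("weighted_cross_entropy: probs must sum to 1 (got ", sum(probs), ")")
  if (label < 1 || label > length(probs))
    stop("weighted_cross_entropy: label out of range")
  -weights[[label]] * log(probs[[label]])
}

#' Training configuration
#'
#' Defaults follow the reference protocol: 85 epochs, batch size 8, SGD
#' (momentum 0.9), learning rate halved when the validation loss plateaus,
#' early stopping with restoration of the best checkpoint, and four seeds.
#'
#' @param epochs Maximum epochs (85).
#' @param batch_size Minibatch size (8).
#' @param learning_rate Initial learning rate; `NULL` uses the model's
#'   per-architecture default.
#' @param optimizer `"sgd"` (the study protocol: stochastic gradient
#'   descent with momentum) or `"adam"` (adaptive-moment steps; used by the
#'   desk-scale overfit checks where plain SGD converges too slowly at the
#'   reduced widths).
#' @param momentum SGD momentum (0.9).
#' @param plateau_factor Learning-rate multiplier on plateau (0.5).
#' @param plateau_patience Epochs without improvement before halving (5).
#' @param early_stop_patience Epochs without improvement before stopping (12).
#' @param min_delta Minimum loss decrease counted as improvement (1e-4).
#' @param class_weights Per-class loss weights; `NULL` for computed
#'   inverse-frequency weights, or a vector, or `FALSE` for unweighted.
#' @param seeds Seeds for repeated runs (default 0:3).
#' @param target_train_acc Optional: stop as soon as the evaluation-mode
#'   training accuracy reaches this value (used by overfit smoke checks).
#' @param clip_norm Global gradient-norm clip (5; `NULL` disables).
#' @param warmup_epochs Epochs run at a quarter of the learning rate before
#'   the full rate applies (0 disables).
#' @param max_seconds Wall-clock training budget; the epoch loop stops once
#'   it is exceeded (`Inf` disables). Used by the desk-scale smoke checks,
#'   which allot each run a fixed time envelope.
#' @return An `hcn_training_config`.
#' @export
training_config <- function(epochs = 85L, batch_size = 8L, learning_rate = NULL,
                            optimizer = c("sgd", "adam"),
                            momentum = 0.9, plateau_factor = 0.5,
                            plateau_patience = 5L, early_stop_patience = 12L,
                            min_delta = 1e-4, class_weights = NULL,
                            seeds = 0:3, target_train_acc = NULL, clip_norm = 5,
                            warmup_epochs = 0L, max_seconds = Inf) {
  optimizer <- match.arg(optimizer)
  stopifnot(plateau_factor > 0, plateau_factor < 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 momentum = momentum,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, class_weights = class_weights,
                 seeds = seeds, target_train_acc = target_train_acc,
                 clip_norm = clip_norm, warmup_epochs = as.integer(warmup_epochs),
                 max_seconds = max_seconds),
            class = "hcn_training_config")
}

# stack a list of cuboids into batch arrays + integer labels
.stack_cuboids <- function(cuboids, classes) {
  n <- length(cuboids)
  d <- dim(cuboids[[1]]$data)
  rgb <- array(0, c(n, d))
  flow <- array(0, c(n, d[1:3], dim(cuboids[[1]]$flow)[4]))
  y <- integer(n)
  for (i in seq_len(n)) {
    rgb[i, , , , ] <- cuboids[[i]]$data
    flow[i, , , , ] <- cuboids[[i]]$flow
    y[i] <- match(as.character(cuboids[[i]]$label), classes)
  }
  if (anyNA(y)) stop("cuboid label outside the class set")
  list(rgb = rgb, flow = flow, y = y)
}

.batch_rows <- function(x, idx) {
  d <- dim(x)
  out <- x[idx, , , , , drop = FALSE]
  out
}

# forward in inference mode over a stacked set, in minibatches
.predict_stacked <- function(model, data, batch_size = 16L) {
  n <- dim(data$rgb)[1]
  K <- model$spec$n_classes
  probs <- matrix(0, n, K)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    logits <- graph_forward(model, list(rgb = .batch_rows(data$rgb, idx),
                                        flow = .batch_rows(data$flow, idx)),
                            training = FALSE)
    probs[idx, ] <- softmax(logits)
    at <- at + batch_size
  }
  probs
}

#' Train a model on a dataset split
#'
#' Runs class-weighted softmax cross-entropy training with SGD + momentum.
#' The learning rate is multiplied by `plateau_factor` whenever the
#' validation loss fails to improve for `plateau_patience` epochs; training
#' stops early after `early_stop_patience` epochs without improvement and
#' the best-validation checkpoint is restored. Fully reproducible given
#' `(seed, cfg)`.
#'
#' @param model A built model (see [build_model()]).
#' @param split A [dataset_split()] whose cuboids carry `data` and `flow`.
#' @param cfg An [training_config()].
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param classes Class labels in index order; default: sorted labels seen
#'   in the training split.
#' @param verbose Print one line per epoch.
#' @return An `hcn_fit`: the trained model, per-epoch `history` tibble,
#'   configuration and seed.
#' @export
train <- function(model, split, cfg = training_config(), seed = 0L,
                  classes = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "hcn_model"), inherits(split, "dataset_split"))
  if (!length(split$train)) stop("train: empty training split")
  classes <- classes %||%
    sort(unique(vapply(split$train, function(cb) as.character(cb$label), character(1))))
  if (length(classes) > model$spec$n_classes)
    stop("train: more classes than model outputs")
  tr <- .stack_cuboids(split$train, classes)
  va <- if (length(split$validation)) .stack_cuboids(split$validation, classes)
  cw <- cfg$class_weights
  if (is.null(cw)) {
    counts <- tabulate(tr$y, nbins = model$spec$n_classes)
    counts[counts == 0] <- 1L
    cw <- sum(counts) / (length(counts) * counts)
  } else if (identical(cw, FALSE)) {
    cw <- rep(1, model$spec$n_classes)
  }
  lr <- cfg$learning_rate %||% model$spec$learning_rate
  set.seed(seed)
  t_start <- Sys.time()
  materialize_params(model)
  n <- length(tr$y)
  calib <- seq_len(min(2L * cfg$batch_size, n))
  calibrate_init(model, list(rgb = .batch_rows(tr$rgb, calib),
                             flow = .batch_rows(tr$flow, calib)))
  K <- model$spec$n_classes
  best <- list(loss = Inf, epoch = 0L, weights = NULL, state = NULL)
  stall <- 0L
  step <- 0L
  hist <- vector("list", cfg$epochs)
  out_of_time <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    at <- 1L
    ep_loss <- 0; ep_hits <- 0
    while (at <= n) {
      if (as.numeric(Sys.time() - t_start, units = "secs") > cfg$max_seconds) {
        out_of_time <- TRUE
        break
      }
      idx <- ord[at:min(n, at + cfg$batch_size - 1L)]
      B <- length(idx)
      logits <- graph_forward(model, list(rgb = .batch_rows(tr$rgb, idx),
                                          flow = .batch_rows(tr$flow, idx)),
                              training = TRUE)
      p <- softmax(logits)
      yb <- tr$y[idx]
      wb <- cw[yb]
      pick <- cbind(seq_len(B), yb)
      ep_loss <- ep_loss + sum(-wb * log(pmax(p[pick], 1e-12)))
      ep_hits <- ep_hits + sum(max.col(p, ties.method = "first") == yb)
      dlogits <- p * wb / B
      dlogits[pick] <- dlogits[pick] - wb / B
      graph_zero_grads(model)
      graph_backward(model, dlogits)
      graph_clip_grads(model, cfg$clip_norm)
      lr_eff <- if (epoch <= cfg$warmup_epochs) lr / 4 else lr
      step <- step + 1L
      if (identical(cfg$optimizer, "adam")) {
        graph_adam_step(model, lr_eff, step)
      } else {
        graph_sgd_step(model, lr_eff, cfg$momentum)
      }
      at <- at + cfg$batch_size
    }
    # running (batch-mode) training metrics; an evaluation-mode confirmation
    # pass is run only when an accuracy target is within reach
    train_loss <- ep_loss / n
    train_acc <- ep_hits / n
    if (!is.null(cfg$target_train_acc) && train_acc >= cfg$target_train_acc - 0.25) {
      pt <- .predict_stacked(model, tr)
      train_acc <- mean(max.col(pt, ties.method = "first") == tr$y)
    }
    if (!is.null(va)) {
      pv <- .predict_stacked(model, va)
      pick <- cbind(seq_along(va$y), va$y)
      val_loss <- -mean(cw[va$y] * log(pmax(pv[pick], 1e-12)))
      val_acc <- mean(max.col(pv, ties.method = "first") == va$y)
    } else {
      val_loss <- train_loss
      val_acc <- train_acc
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = train_loss, train_acc = train_acc,
                                val_loss = val_loss, val_acc = val_acc)
    if (verbose)
      message(sprintf("epoch %3d lr %.2e loss %.4f acc %.3f val %.4f/%.3f",
                      epoch, lr, train_loss, train_acc, val_loss, val_acc))
    if (!is.finite(val_loss)) val_loss <- Inf
    if (!is.null(cfg$target_train_acc) && train_acc >= cfg$target_train_acc) {
      best <- list(loss = val_loss, epoch = epoch,
                   weights = model_get_weights(model),
                   state = model_get_state(model))
      break
    }
    if (val_loss < best$loss - cfg$min_delta) {
      best <- list(loss = val_loss, epoch = epoch,
                   weights = model_get_weights(model),
                   state = model_get_state(model))
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall %% cfg$plateau_patience == 0L) lr <- lr * cfg$plateau_factor
      if (stall >= cfg$early_stop_patience) break
    }
    if (out_of_time ||
        as.numeric(Sys.time() - t_start, units = "secs") > cfg$max_seconds)
      break
  }
  if (!is.null(best$weights)) {
    model_set_weights(model, best$weights)
    model_set_state(model, best$state)
  }
  structure(list(model = model, history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 config = cfg, seed = seed, classes = classes,
                 class_weights = cw),
            class = "hcn_fit")
}

#' @export
print.hcn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<trained %s (%s), seed %d: %d epochs, best val loss %.4f (epoch %d)>\n",
              x$model$spec$name, x$model$spec$variant, x$seed, nrow(h),
              x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' Class probabilities of a fitted model on a list of cuboids
#'
#' @param fit An `hcn_fit` (or built model).
#' @param cuboids List of cuboids with `data` and `flow`.
#' @param batch_size Minibatch size for inference.
#' @return `N x K` probability matrix.
#' @export
predict_cuboids <- function(fit, cuboids, batch_size = 16L) {
  model <- if (inherits(fit, "hcn_fit")) fit$model else fit
  classes <- if (inherits(fit, "hcn_fit")) fit$classes else NULL
  data <- .stack_cuboids(cuboids, classes %||%
    sort(unique(vapply(cuboids, function(cb) as.character(cb$label), character(1)))))
  .predict_stacked(model, data, batch_size)
}
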