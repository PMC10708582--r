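# Matched-configuration ablation driver: stream-variant comparison,
# input-kind comparison (grayscale / raw / nightified) and temporal-length
# sweeps, all run under identical seeds so rows are directly comparable.

#' Convert the RGB stream of a split to one input kind
#'
#' @param split A [dataset_split()].
#' @param kind `"raw"`, `"grayscale"` (ITU-R 601 luminance, single channel)
#'   or `"nightified"` (channels weighted by `ref / 255`).
#' @param ref Night reference triple (on `[0, 255]`) for `"nightified"`.
#' @return The transformed split.
#' @export
transform_input_kind <- function(split, kind = c("raw", "grayscale", "nightified"),
                                 ref = c(110, 110, 110)) {
  kind <- match.arg(kind)
  if (kind == "raw") return(split)
  fx <- function(cb) {
    d <- cb$data
    if (kind == "grayscale") {
      g <- 0.299 * d[, , , 1, drop = FALSE] + 0.587 * d[, , , 2, drop = FALSE] +
        0.114 * d[, , , 3, drop = FALSE]
      cb$data <- g
    } else {
      for (cc in 1:3) d[, , , cc] <- d[, , , cc] * ref[cc] / 255
      cb$data <- d
    }
    cb
  }
  for (part in c("train", "validation", "test"))
    split[[part]] <- lapply(split[[part]], fx)
  split$class_counts <- dataset_split(split$train, split$validation,
                                      split$test)$class_counts
  split
}

#' Run a matched ablation and tabulate the results
#'
#' Each row trains one configuration on synthetic data generated under the
#' same base seed and reports the test-set metrics:
#' * `variant`: feature-sharing vs standalone streams of one architecture;
#' * `input_kind`: grayscale vs raw vs nightified RGB input;
#' * `temporal_length`: T in {4, 8, 16} (the SRS temporal crop scales with
#'   T automatically: 1+1, 2+2, 4+4 frames).
#'
#' @param axis Ablation axis.
#' @param model Architecture name (see [model_spec()]).
#' @param synth A [synthetic_spec()] describing the data conditions.
#' @param cfg A [training_config()].
#' @param seed Seed shared by every row.
#' @param filter_scale Width multiplier passed to [model_spec()].
#' @param temporal_lengths T values for the `temporal_length` axis.
#' @return Tibble, one row per configuration, with accuracy and the other
#'   report metrics.
#' @export
ablate <- function(axis = c("variant", "input_kind", "temporal_length"),
                   model = "baseline", synth = synthetic_spec(),
                   cfg = training_config(), seed = 0L, filter_scale = 1,
                   temporal_lengths = c(4L, 8L, 16L)) {
  axis <- match.arg(axis)
  run_one <- function(label, split, spec) {
    net <- build_model(spec)
    fit <- train(net, split, cfg, seed = seed)
    probs <- predict_cuboids(fit, split$test)
    rep <- evaluate(probs, vapply(split$test, function(cb) as.character(cb$label),
                                  character(1)), classes = fit$classes)
    tibble::tibble(configuration = label,
                   accuracy = rep$accuracy, micro_AP = rep$micro_AP,
                   precision = rep$precision, recall = rep$recall, F1 = rep$F1,
                   micro_AUC = rep$micro_AUC, macro_AUC = rep$macro_AUC,
                   parameters = count_parameters(net), seed = seed)
  }
  in_shape <- function(s, C = s$C) c(s$T, s$H, s$W, C)
  rows <- switch(axis,
    variant = {
      split <- generate_dataset(synth)
      lapply(c("sharing", "standalone"), function(v)
        run_one(v, split, model_spec(model, v, input_shape = in_shape(synth),
                                     filter_scale = filter_scale)))
    },
    input_kind = {
      split <- generate_dataset(synth)
      lapply(c("grayscale", "raw", "nightified"), function(k) {
        sp <- transform_input_kind(split, k)
        C <- if (k == "grayscale") 1L else 3L
        run_one(k, sp, model_spec(model, "sharing", input_shape = in_shape(synth, C),
                                  filter_scale = filter_scale))
      })
    },
    temporal_length = {
      lapply(temporal_lengths, function(tt) {
        s2 <- synth; s2$T <- as.integer(tt)
        split <- generate_dataset(s2)
        run_one(paste0("T=", tt), split,
                model_spec(model, "sharing", input_shape = in_shape(s2),
                           filter_scale = filter_scale))
      })
    })
  do.call(rbind, rows)
}
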