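# Layer-graph construction and execution.
#
# A model is a directed acyclic graph of layer nodes built in topological
# order. Shapes and parameter shapes are inferred at build time, so parameter
# and FLOP accounting never require materialized weights; weights are
# allocated lazily by materialize_params() before training or prediction.

graph_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$tags <- list()
  g
}

graph_add <- function(g, type, inputs = integer(0), cfg = list(),
                      name = NULL, tag = NULL) {
  force(inputs)   # nested graph_add() calls must register before this node
  id <- length(g$nodes) + 1L
  in_shapes <- lapply(inputs, function(i) g$nodes[[i]]$shape)
  shape <- layer_out_shape(type, cfg, if (length(in_shapes)) in_shapes else list(cfg$shape))
  if (type == "input") shape <- cfg$shape
  node <- list(id = id, type = type, inputs = as.integer(inputs), cfg = cfg,
               name = name %||% paste0(type, "_", id), shape = shape,
               pshapes = layer_param_shapes(type, cfg,
                                            if (length(in_shapes)) in_shapes else list(cfg$shape)),
               layer = new_layer(type, cfg))
  g$nodes[[id]] <- node
  if (!is.null(tag)) g$tags[[tag]] <- id
  id
}

graph_shape <- function(g, id) g$nodes[[id]]$shape

#' Number of trainable parameters in a built model
#'
#' Counts every trainable scalar, including biases and the scale/shift
#' parameters of batch normalization, mirroring the "trainable parameters"
#' line of common deep-learning framework summaries.
#'
#' @param model A model built by [build_model()].
#' @return Integer-valued count (as a double, counts exceed
#'   `.Machine$integer.max / 2` for some architectures only in principle).
#' @export
count_parameters <- function(model) {
  tot <- 0
  for (node in model$graph$nodes)
    for (ps in node$pshapes) tot <- tot + prod(ps)
  tot
}

#' FLOPS figure under the parameter-doubling convention
#'
#' Returns `2 x` the number of trainable parameters in multiply-accumulate
#' bearing layers (convolutions, dense layers, attention projections and
#' recurrent kernels; normalization parameters are excluded). This is a
#' model-complexity figure, not a per-inference dense operation count; it is
#' the convention under which the reference accounting tables for these
#' architectures were produced. Recurrent models additionally spend FLOPs on
#' time-step unrolling that this figure does not include.
#'
#' @param model A built model.
#' @return FLOPS figure (numeric).
#' @export
count_flops <- function(model) {
  mac_types <- c("conv3d", "dense", "mha", "bilstm")
  tot <- 0
  for (node in model$graph$nodes)
    if (node$type %in% mac_types)
      for (ps in node$pshapes) tot <- tot + prod(ps)
  2 * tot
}

#' Per-module output shapes of a built model
#'
#' Shapes are recorded at the exit of each joint-processing module (or its
#' mirrored position in standalone variants), in T x H x W x C order,
#' matching the published per-module output-size tables.
#'
#' @param model A built model.
#' @return A list of integer vectors `c(T, H, W, C)`, one per module.
#' @export
layer_output_shapes <- function(model) {
  lapply(model$module_outputs, function(id) model$graph$nodes[[id]]$shape$dim)
}

#' @noRd
model_is_materialized <- function(model) {
  for (node in model$graph$nodes)
    if (length(node$pshapes)) return(!is.null(node$layer$params))
  TRUE
}

#' @noRd
materialize_params <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (node in model$graph$nodes) {
    in_shapes <- lapply(node$inputs, function(i) model$graph$nodes[[i]]$shape)
    if (!length(in_shapes)) in_shapes <- list(node$cfg$shape)
    layer_init_params(node$layer, in_shapes)
  }
  invisible(model)
}

#' @noRd
graph_forward <- function(model, inputs, training = FALSE) {
  g <- model$graph
  values <- vector("list", length(g$nodes))
  for (node in g$nodes) {
    if (node$type == "input") {
      values[[node$id]] <- inputs[[node$cfg$key]]
    } else {
      ins <- lapply(node$inputs, function(i) values[[i]])
      values[[node$id]] <- layer_forward(node$layer, ins, training)
    }
  }
  g$values <- values   # kept on the graph environment for introspection
  values[[model$output_id]]
}

#' @noRd
#' Data-dependent initialization: rescale convolution and dense weights so
#' each layer's output has unit standard deviation on a calibration batch.
#' The normalization-free Inception-only architectures otherwise start with
#' exploding activation scales. Rescaling is parameter-count neutral and,
#' through the positively homogeneous conv/pool/rectifier chain, a few
#' passes suffice.
calibrate_init <- function(model, inputs, tol = 0.05) {
  g <- model$graph
  targets <- Filter(function(node)
    node$type %in% c("conv3d", "dense") && length(node$layer$params), g$nodes)
  # sequential: each layer is corrected with all upstream layers already
  # fixed, so a single measurement per layer is exact
  for (node in targets) {
    values <- vector("list", length(g$nodes))
    for (nd in g$nodes) {
      if (nd$id > node$id) break
      values[[nd$id]] <- if (nd$type == "input") inputs[[nd$cfg$key]] else
        layer_forward(nd$layer, lapply(nd$inputs, function(i) values[[i]]),
                      training = TRUE)
    }
    # the amplification is capped so a near-constant input stream cannot
    # have its noise blown up to unit variance
    s <- max(stats::sd(values[[node$id]]), 0.1)
    if (is.finite(s) && abs(s - 1) > tol) {
      lay <- node$layer
      lay$params <- lapply(lay$params, function(pp) pp / s)
    }
  }
  invisible(model)
}

#' @noRd
graph_backward <- function(model, dout) {
  g <- model$graph
  n <- length(g$nodes)
  dvals <- vector("list", n)
  dvals[[model$output_id]] <- dout
  for (id in rev(seq_len(n))) {
    node <- g$nodes[[id]]
    dy <- dvals[[id]]
    if (is.null(dy) || node$type == "input") next
    dins <- layer_backward(node$layer, dy, n_inputs = length(node$inputs))
    for (j in seq_along(node$inputs)) {
      tgt <- node$inputs[[j]]
      dvals[[tgt]] <- if (is.null(dvals[[tgt]])) dins[[j]] else dvals[[tgt]] + dins[[j]]
    }
    dvals[[id]] <- NULL   # free memory as we go
  }
  invisible(model)
}

#' @noRd
graph_zero_grads <- function(model) {
  for (node in model$graph$nodes) .zero_grads(node$layer)
  invisible(model)
}

#' @noRd
graph_clip_grads <- function(model, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(invisible(model))
  ss <- 0
  for (node in model$graph$nodes) {
    lay <- node$layer
    if (length(lay$params))
      for (g in lay$grads) ss <- ss + sum(g * g)
  }
  gn <- sqrt(ss)
  if (is.finite(gn) && gn > max_norm) {
    sc <- max_norm / gn
    for (node in model$graph$nodes) {
      lay <- node$layer
      if (length(lay$params))
        lay$grads <- lapply(lay$grads, function(g) g * sc)
    }
  } else if (!is.finite(gn)) {
    for (node in model$graph$nodes) {
      lay <- node$layer
      if (length(lay$params))
        lay$grads <- lapply(lay$grads, function(g) { g[] <- 0; g })
    }
  }
  invisible(model)
}

#' @noRd
graph_sgd_step <- function(model, lr, momentum = 0.9) {
  for (node in model$graph$nodes) {
    lay <- node$layer
    if (!length(lay$params)) next
    if (is.null(lay$velocity))
      lay$velocity <- lapply(lay$params, function(p) array(0, dim = dim(p) %||% length(p)))
    for (nm in names(lay$params)) {
      lay$velocity[[nm]] <- momentum * lay$velocity[[nm]] - lr * lay$grads[[nm]]
      lay$params[[nm]] <- lay$params[[nm]] + lay$velocity[[nm]]
    }
  }
  invisible(model)
}

#' @noRd
graph_adam_step <- function(model, lr, step, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (node in model$graph$nodes) {
    lay <- node$layer
    if (!length(lay$params)) next
    if (is.null(lay$adam_m)) {
      lay$adam_m <- lapply(lay$params, function(p) array(0, dim = dim(p) %||% length(p)))
      lay$adam_v <- lay$adam_m
    }
    for (nm in names(lay$params)) {
      g <- lay$grads[[nm]]
      lay$adam_m[[nm]] <- beta1 * lay$adam_m[[nm]] + (1 - beta1) * g
      lay$adam_v[[nm]] <- beta2 * lay$adam_v[[nm]] + (1 - beta2) * g * g
      lay$params[[nm]] <- lay$params[[nm]] -
        lr * (lay$adam_m[[nm]] / bc1) / (sqrt(lay$adam_v[[nm]] / bc2) + eps)
    }
  }
  invisible(model)
}

#' @noRd
model_get_weights <- function(model) {
  lapply(model$graph$nodes, function(node) node$layer$params)
}

#' @noRd
model_set_weights <- function(model, weights) {
  for (i in seq_along(model$graph$nodes)) {
    model$graph$nodes[[i]]$layer$params <- weights[[i]]
  }
  invisible(model)
}

#' @noRd
model_get_state <- function(model) {
  lapply(model$graph$nodes, function(node) node$layer$state)
}

#' @noRd
model_set_state <- function(model, states) {
  for (i in seq_along(model$graph$nodes))
    model$graph$nodes[[i]]$layer$state <- states[[i]]
  invisible(model)
}

#' Softmax over the rows of a score matrix
#' @noRd
softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
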