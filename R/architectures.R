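# Builders for the five dual-stream architectures, each in feature-sharing
# and standalone form.
#
# The two network streams (nightified RGB cuboids and encoded optical flow)
# are processed by primary modules; in the feature-sharing variants the
# stream outputs are combined (addition or concatenation) and jointly
# processed at every module boundary, while standalone variants replicate
# the joint blocks inside each stream and merge only before the common
# fully-connected stack. Per-module output geometry follows the published
# module tables; interior widths come from the calibrated tables in
# widths.R.

#' Model specification for a dual-stream behavior classifier
#'
#' @param name One of `"baseline"`, `"civ3d_mha"`, `"civ3d_bilstm"`,
#'   `"srs"`, `"crs"`.
#' @param variant `"sharing"` (joint processing between the streams at every
#'   module boundary) or `"standalone"` (conventional independent streams,
#'   late fusion).
#' @param input_shape Per-stream cuboid geometry `c(T, H, W, C)`. The
#'   reference geometry is `c(8, 96, 128, 3)`.
#' @param n_classes Number of behavior classes (default 8).
#' @param filter_scale Multiplier applied to every internal width (filters,
#'   joint widths, attention and recurrent widths, FC units). `1` reproduces
#'   the reference accounting; fractions give desk-scale trainable models.
#' @param learning_rate Optimizer learning rate; defaults to the published
#'   per-architecture value (0.0005 for the baseline, 0.001 otherwise).
#' @param attention_scale `"sqrt_dk"` (scaled dot-product convention) or
#'   `"dk"` to divide attention scores by d_k itself.
#' @param dropout_rate Dropout rate of the primary blocks, joint blocks and
#'   first FC layer (reference value 0.2). At strongly reduced
#'   `filter_scale` a proportionally smaller rate keeps the narrow layers
#'   trainable.
#' @return A `hcn_model_spec` object.
#' @export
model_spec <- function(name = c("baseline", "civ3d_mha", "civ3d_bilstm", "srs", "crs"),
                       variant = c("sharing", "standalone"),
                       input_shape = c(8L, 96L, 128L, 3L),
                       n_classes = 8L,
                       filter_scale = 1,
                       learning_rate = NULL,
                       attention_scale = c("sqrt_dk", "dk"),
                       dropout_rate = 0.2) {
  name <- match.arg(name)
  variant <- match.arg(variant)
  attention_scale <- match.arg(attention_scale)
  stopifnot(length(input_shape) == 4, all(input_shape >= 1), filter_scale > 0)
  if (is.null(learning_rate))
    learning_rate <- if (name == "baseline") 5e-4 else 1e-3
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  spec <- list(
    name = name, variant = variant, dropout_rate = dropout_rate,
    input_shape = as.integer(input_shape),
    n_classes = as.integer(n_classes),
    filter_scale = filter_scale,
    learning_rate = learning_rate,
    attention_scale = attention_scale,
    combine = switch(name, baseline = "add", civ3d_mha = "add",
                     civ3d_bilstm = "add", srs = "concat", crs = "concat"),
    primary_filters = switch(name,
      baseline = c(16L, 32L, 64L, 128L),
      civ3d_mha = c(16L, 32L, 64L, 128L),
      civ3d_bilstm = c(16L, 32L, 64L, 128L),
      srs = c(8L, 16L, 32L, 64L, 64L, 128L),
      crs = c(12L, 24L, 48L, 96L, 192L)),
    kernels = switch(name,
      baseline = c(5L, 3L, 5L, 5L),
      civ3d_mha = c(7L, 5L, 5L, 3L),
      civ3d_bilstm = c(7L, 5L, 5L, 3L),
      srs = NULL, crs = NULL),   # purely Inception-based: kernels fixed by the block
    fc_units = c(512L, 64L)
  )
  class(spec) <- "hcn_model_spec"
  spec
}

#' @export
print.hcn_model_spec <- function(x, ...) {
  cat(sprintf("<model spec> %s (%s)\n", x$name, x$variant))
  cat(sprintf("  input %s per stream, %d classes, lr %g, filter scale %g\n",
              paste(x$input_shape, collapse = "x"), x$n_classes,
              x$learning_rate, x$filter_scale))
  invisible(x)
}

.sc <- function(w, scale) {
  # reduced-width instantiations floor at 4 channels so no branch collapses
  # to a near-degenerate bottleneck
  out <- if (scale == 1) as.integer(w) else pmax(4L, as.integer(round(w * scale)))
  names(out) <- names(w)
  out
}

# -------------------------------------------------------- block emitters --

# Primary CNN block: conv-BN-LReLU(-dropout) twice; kernels (m, m2); the
# second conv carries the configured stride.
emit_primary_block <- function(g, x, n1, n2, m1, m2, stride1, stride2,
                               dropout = 0.2, name = "primary") {
  shp <- graph_shape(g, x)$dim
  if (m1 > 2 * shp[2] + 1 || m1 > 2 * shp[3] + 1)
    stop("primary block '", name, "': kernel ", m1,
         " exceeds spatial extent ", shp[2], "x", shp[3])
  x <- graph_add(g, "conv3d", x, list(kernel = rep(m1, 3L), stride = stride1,
                                      out_ch = n1), name = paste0(name, "_c1"))
  x <- graph_add(g, "batchnorm", x, name = paste0(name, "_bn1"))
  x <- graph_add(g, "leaky_relu", x, list(alpha = 0.1))
  if (dropout > 0) x <- graph_add(g, "dropout", x, list(rate = dropout))
  x <- graph_add(g, "conv3d", x, list(kernel = rep(m2, 3L), stride = stride2,
                                      out_ch = n2), name = paste0(name, "_c2"))
  x <- graph_add(g, "batchnorm", x, name = paste0(name, "_bn2"))
  x <- graph_add(g, "leaky_relu", x, list(alpha = 0.1))
  if (dropout > 0) x <- graph_add(g, "dropout", x, list(rate = dropout))
  x
}

# Dense-dropout joint block (baseline): expansion dense, dropout, projection
# to the module's output width (k * n channels).
emit_dense_joint <- function(g, x, width, out_ch, dropout = 0.2, name = "joint") {
  x <- graph_add(g, "dense", x, list(units = width), name = paste0(name, "_d1"))
  x <- graph_add(g, "leaky_relu", x, list(alpha = 0.1))
  if (dropout > 0) x <- graph_add(g, "dropout", x, list(rate = dropout))
  graph_add(g, "dense", x, list(units = out_ch), name = paste0(name, "_d2"))
}

# Inception v3 block-D in 3-D (grid reduction): two convolutional branches
# with stride-2 exits plus a pooling branch, concatenated on channels.
emit_inception_v3d <- function(g, x, w, stride, name = "incd") {
  cv <- function(x, ch, k, s = c(1L, 1L, 1L), suff) {
    x <- graph_add(g, "conv3d", x, list(kernel = rep(k, 3L), stride = s,
                                        out_ch = ch), name = paste0(name, suff))
    graph_add(g, "leaky_relu", x, list(alpha = 0.1))
  }
  b1 <- cv(x, w[["a"]], 1L, suff = "_1a")
  b1 <- cv(b1, w[["b"]], 3L, stride, "_1b")
  b2 <- cv(x, w[["c"]], 1L, suff = "_2a")
  b2 <- cv(b2, w[["d"]], 3L, suff = "_2b")
  b2 <- cv(b2, w[["e"]], 3L, stride, "_2c")
  b3 <- graph_add(g, "maxpool3d", x, list(stride = stride), name = paste0(name, "_pool"))
  b3 <- cv(b3, w[["p"]], 1L, suff = "_3p")
  graph_add(g, "concat", c(b1, b2, b3), name = paste0(name, "_cat"))
}

# Inception v1 3-D block without the lone 1x1x1 branch: 1x1->3^3, 1x1->5^3,
# pool->1x1, concatenated. Branch activations are leaky (the published
# tables pin ReLU only for the pre-FC activation); hard rectifiers inside
# the normalization-free blocks die under SGD at desk scale.
emit_inception_v1 <- function(g, x, w, stride, activation = "lrelu", name = "incv1") {
  act <- function(x) graph_add(g, "leaky_relu", x,
                               list(alpha = if (activation == "relu") 0 else 0.1))
  cv <- function(x, ch, k, s = c(1L, 1L, 1L), suff) {
    act(graph_add(g, "conv3d", x, list(kernel = rep(k, 3L), stride = s,
                                       out_ch = ch), name = paste0(name, suff)))
  }
  shp <- graph_shape(g, x)$dim
  if (5L > 2 * shp[2] + 1 || 5L > 2 * shp[3] + 1)
    stop("inception block '", name, "': 5x5x5 branch exceeds spatial extent ",
         shp[2], "x", shp[3])
  b1 <- cv(x, w[["a"]], 1L, suff = "_1a")
  b1 <- cv(b1, w[["b"]], 3L, stride, "_1b")
  b2 <- cv(x, w[["c"]], 1L, suff = "_2a")
  b2 <- cv(b2, w[["d"]], 5L, stride, "_2b")
  b3 <- graph_add(g, "maxpool3d", x, list(stride = stride), name = paste0(name, "_pool"))
  b3 <- cv(b3, w[["p"]], 1L, suff = "_3p")
  out <- graph_add(g, "concat", c(b1, b2, b3), name = paste0(name, "_cat"))
  # parameter-free pooled identity side-path for optimization conditioning
  shortcut <- graph_add(g, "maxpool3d", x, list(stride = stride))
  graph_add(g, "pad_residual", c(out, shortcut), name = paste0(name, "_res"))
}

# Self-attention block over the end features of one stream: batch norm in
# place of layer norm, multi-head attention and a bias-free MLP, both with
# residual connections; token sequence is the flattened T*H*W grid.
emit_attention_block <- function(g, x, d_k, heads, mlp_width, scale, name = "attn") {
  shp <- graph_shape(g, x)$dim
  tok <- graph_add(g, "to_tokens", x, name = paste0(name, "_tok"))
  b1 <- graph_add(g, "batchnorm", tok, name = paste0(name, "_bn1"))
  att <- graph_add(g, "mha", b1, list(d_k = d_k, heads = heads, scale = scale),
                   name = paste0(name, "_mha"))
  r1 <- graph_add(g, "add", c(tok, att))
  b2 <- graph_add(g, "batchnorm", r1, name = paste0(name, "_bn2"))
  m <- graph_add(g, "dense", b2, list(units = mlp_width, bias = FALSE),
                 name = paste0(name, "_mlp1"))
  m <- graph_add(g, "leaky_relu", m, list(alpha = 0.1))
  m <- graph_add(g, "dense", m, list(units = shp[4], bias = FALSE),
                 name = paste0(name, "_mlp2"))
  r2 <- graph_add(g, "add", c(r1, m))
  graph_add(g, "from_tokens", r2, list(t = shp[1], h = shp[2], w = shp[3]),
            name = paste0(name, "_untok"))
}

# The named activation (ReLU for the purely Inception-based models, leaky
# ReLU otherwise) is applied to the features entering the FC stack; the
# activations between the dense layers are always leaky — hard rectifiers
# there can die wholesale and permanently zero every gradient.
emit_fc_head <- function(g, x, fc_units, n_classes, activation = "lrelu",
                         dropout = 0.2) {
  alpha <- if (activation == "relu") 0 else 0.1
  x <- graph_add(g, "leaky_relu", x, list(alpha = alpha))
  for (i in seq_along(fc_units)) {
    x <- graph_add(g, "dense", x, list(units = fc_units[i]),
                   name = paste0("fc", i))
    x <- graph_add(g, "leaky_relu", x, list(alpha = 0.1))
    if (dropout > 0 && i == 1L)
      x <- graph_add(g, "dropout", x, list(rate = dropout))
  }
  graph_add(g, "dense", x, list(units = n_classes, glorot = TRUE),
            name = "logits")
}

# ------------------------------------------------------------ assemblers --

#' Build a trainable dual-stream model from its specification
#'
#' Constructs the full layer graph (both input streams, primary modules,
#' joint processing or its standalone replication, and the classification
#' head). The returned model supports parameter and FLOP accounting without
#' weight allocation; call [train()] or [predict_model()] to use it.
#'
#' @param spec A [model_spec()].
#' @return An object of class `hcn_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "hcn_model_spec"))
  model <- switch(spec$name,
    baseline = build_baseline(spec),
    civ3d_mha = build_civ3d(spec, head = "mha"),
    civ3d_bilstm = build_civ3d(spec, head = "bilstm"),
    srs = build_srs(spec),
    crs = build_crs(spec))
  model$spec <- spec
  class(model) <- "hcn_model"
  model
}

#' @export
print.hcn_model <- function(x, ...) {
  cat(sprintf("<%s model, %s variant>\n", x$spec$name, x$spec$variant))
  cat(sprintf("  parameters: %s | FLOPS figure: %.2fe6\n",
              format(count_parameters(x), big.mark = ","),
              count_flops(x) / 1e6))
  shp <- layer_output_shapes(x)
  for (i in seq_along(shp))
    cat(sprintf("  module %d: %s\n", i, paste(shp[[i]], collapse = " x ")))
  invisible(x)
}

.inputs <- function(g, spec) {
  ishape <- shape_thwc(spec$input_shape[1], spec$input_shape[2],
                       spec$input_shape[3], spec$input_shape[4])
  list(rgb = graph_add(g, "input", cfg = list(key = "rgb", shape = ishape)),
       flow = graph_add(g, "input", cfg = list(key = "flow", shape = ishape)))
}

build_baseline <- function(spec) {
  g <- graph_new()
  sc <- function(w) .sc(w, spec$filter_scale)
  ins <- .inputs(g, spec)
  n <- sc(spec$primary_filters)
  m <- spec$kernels
  jw <- sc(.hcn_baseline_joint_widths[[spec$variant]])
  out_ch <- sc(round(1.5 * spec$primary_filters))
  stride1 <- list(c(1L, 2L, 2L), c(1L, 1L, 1L), c(1L, 1L, 1L), c(1L, 1L, 1L))
  stride2 <- list(c(2L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 2L), c(1L, 2L, 2L))
  streams <- ins
  module_outputs <- integer(4)
  for (i in 1:4) {
    blocks <- lapply(names(streams), function(s)
      emit_primary_block(g, streams[[s]], n[i], n[i], m[i], m[i],
                         stride1[[i]], stride2[[i]], dropout = spec$dropout_rate,
                         name = sprintf("m%d_%s", i, s)))
    names(blocks) <- names(streams)
    if (spec$variant == "sharing") {
      comb <- graph_add(g, "add", c(blocks$rgb, blocks$flow),
                        name = sprintf("m%d_add", i))
      joint <- emit_dense_joint(g, comb, jw[i], out_ch[i],
                                dropout = spec$dropout_rate,
                                name = sprintf("m%d_joint", i))
      joint <- graph_add(g, "pad_residual", c(joint, comb),
                         name = sprintf("m%d_res", i))
      module_outputs[i] <- joint
      streams <- list(rgb = joint, flow = joint)
    } else {
      joints <- lapply(names(blocks), function(s) {
        j <- emit_dense_joint(g, blocks[[s]], jw[i], out_ch[i],
                              dropout = spec$dropout_rate,
                              name = sprintf("m%d_joint_%s", i, s))
        graph_add(g, "pad_residual", c(j, blocks[[s]]),
                  name = sprintf("m%d_res_%s", i, s))
      })
      names(joints) <- names(blocks)
      module_outputs[i] <- joints$rgb
      streams <- joints
    }
  }
  trunk <- if (spec$variant == "sharing") streams$rgb else
    graph_add(g, "add", c(streams$rgb, streams$flow), name = "late_fusion")
  flat <- graph_add(g, "flatten", trunk, name = "flatten")
  out <- emit_fc_head(g, flat, sc(spec$fc_units), spec$n_classes,
                      dropout = spec$dropout_rate)
  list(graph = g, output_id = out, input_ids = ins,
       module_outputs = as.list(module_outputs))
}

build_civ3d <- function(spec, head) {
  g <- graph_new()
  sc <- function(w) .sc(w, spec$filter_scale)
  ins <- .inputs(g, spec)
  n <- sc(spec$primary_filters)
  n2 <- sc(round(1.5 * spec$primary_filters))
  m <- spec$kernels
  wkey <- if (spec$variant == "sharing") "sharing" else paste0("standalone_", head)
  ws <- lapply(.hcn_incd_widths[[wkey]], sc)
  dropout <- if (head == "bilstm") 0 else spec$dropout_rate
  stride1 <- list(c(1L, 2L, 2L), c(1L, 1L, 1L), c(1L, 1L, 1L), c(1L, 1L, 1L))
  jstride <- list(c(2L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 2L), c(1L, 2L, 2L))
  streams <- ins
  module_outputs <- integer(4)
  att <- .hcn_attention_defaults
  for (i in 1:4) {
    blocks <- lapply(names(streams), function(s)
      emit_primary_block(g, streams[[s]], n[i], n2[i], m[i], m[i] - 2L,
                         stride1[[i]], c(1L, 1L, 1L), dropout = dropout,
                         name = sprintf("m%d_%s", i, s)))
    names(blocks) <- names(streams)
    if (i == 4L && head == "mha") {
      blocks <- lapply(names(blocks), function(s)
        emit_attention_block(g, blocks[[s]], sc(att$d_k), att$heads,
                             sc(att$mlp_width),
                             scale = if (spec$attention_scale == "dk") "dk" else "sqrt",
                             name = paste0("attn_", s)))
      names(blocks) <- names(streams)
    }
    if (spec$variant == "sharing") {
      comb <- graph_add(g, "add", c(blocks$rgb, blocks$flow),
                        name = sprintf("m%d_add", i))
      joint <- emit_inception_v3d(g, comb, ws[[i]], jstride[[i]],
                                  name = sprintf("m%d_incd", i))
      pool <- graph_add(g, "maxpool3d", comb, list(stride = jstride[[i]]))
      joint <- graph_add(g, "pad_residual", c(joint, pool),
                         name = sprintf("m%d_res", i))
      module_outputs[i] <- joint
      streams <- list(rgb = joint, flow = joint)
    } else {
      joints <- lapply(names(blocks), function(s) {
        j <- emit_inception_v3d(g, blocks[[s]], ws[[i]], jstride[[i]],
                                name = sprintf("m%d_incd_%s", i, s))
        pool <- graph_add(g, "maxpool3d", blocks[[s]], list(stride = jstride[[i]]))
        graph_add(g, "pad_residual", c(j, pool),
                  name = sprintf("m%d_res_%s", i, s))
      })
      names(joints) <- names(blocks)
      module_outputs[i] <- joints$rgb
      streams <- joints
    }
  }
  trunk <- if (spec$variant == "sharing") streams$rgb else
    graph_add(g, "add", c(streams$rgb, streams$flow), name = "late_fusion")
  if (head == "bilstm") {
    tok <- graph_add(g, "to_tokens", trunk, name = "lstm_tokens")
    feat <- graph_add(g, "bilstm", tok, list(hidden = sc(.hcn_bilstm_hidden)),
                      name = "bilstm")
    out <- emit_fc_head(g, feat, sc(spec$fc_units), spec$n_classes,
                        dropout = spec$dropout_rate)
  } else {
    flat <- graph_add(g, "flatten", trunk, name = "flatten")
    out <- emit_fc_head(g, flat, sc(spec$fc_units), spec$n_classes,
                        dropout = spec$dropout_rate)
  }
  list(graph = g, output_id = out, input_ids = ins,
       module_outputs = as.list(module_outputs))
}

#' @noRd
.match_stride <- function(from, to, what) {
  s <- from / to
  if (any(s < 1) || any(s != floor(s)))
    stop("cannot stride flow copy from ", paste(from, collapse = "x"),
         " to ", paste(to, collapse = "x"), " at ", what)
  as.integer(s)
}

build_srs <- function(spec) {
  g <- graph_new()
  sc <- function(w) .sc(w, spec$filter_scale)
  T0 <- spec$input_shape[1]
  crop <- max(1L, T0 %/% 4L)
  if (2L * crop >= T0)
    stop("SRS temporal crop of ", crop, "+", crop,
         " frames leaves no flow frames for T = ", T0)
  ins <- .inputs(g, spec)
  ws <- lapply(.hcn_srs_widths[[spec$variant]], sc)
  fl <- sc(.hcn_srs_widths$flow_width)
  module_outputs <- integer(6)
  if (spec$variant == "sharing") {
    rgb1 <- emit_inception_v1(g, ins$rgb, ws[[1]], c(1L, 1L, 1L), name = "m1_rgb")
    flow1 <- emit_inception_v1(g, ins$flow, ws[[2]], c(1L, 1L, 1L), name = "m1_flow")
    x <- graph_add(g, "concat", c(rgb1, flow1), name = "m1_cat")
    module_outputs[1] <- x
    # one-time temporal crop of the raw flow sequence to its central frames
    fc <- graph_add(g, "temporal_crop", ins$flow, list(head = crop, tail = crop),
                    name = "flow_crop")
    for (i in 2:6) {
      if (i >= 3 && i <= 5) {
        tgt <- graph_shape(g, x)$dim[1:3]
        s <- .match_stride(graph_shape(g, fc)$dim[1:3], tgt,
                           sprintf("SRS module %d", i))
        rf <- graph_add(g, "conv3d", fc, list(kernel = c(1L, 1L, 1L),
                                              stride = s, out_ch = fl),
                        name = sprintf("m%d_flowre", i))
        x <- graph_add(g, "concat", c(x, rf), name = sprintf("m%d_in", i))
      }
      # temporal striding continues while frames remain, so the end
      # geometry (and the FC width) is the same for every supported T
      st <- c(if (graph_shape(g, x)$dim[1] > 1L) 2L else 1L, 2L, 2L)
      x <- emit_inception_v1(g, x, ws[[i + 1]], st, name = sprintf("m%d", i))
      module_outputs[i] <- x
    }
    flat <- graph_add(g, "flatten", x, name = "flatten")
    out <- emit_fc_head(g, flat, sc(spec$fc_units), spec$n_classes,
                        activation = "relu", dropout = spec$dropout_rate)
  } else {
    ends <- list()
    for (s in names(ins)) {
      x <- ins[[s]]
      for (i in 1:6) {
        st <- if (i == 1L) c(1L, 1L, 1L) else
          c(if (graph_shape(g, x)$dim[1] > 1L) 2L else 1L, 2L, 2L)
        x <- emit_inception_v1(g, x, ws[[i]], st,
                               name = sprintf("m%d_%s", i, s))
        if (s == "rgb") module_outputs[i] <- x
      }
      ends[[s]] <- graph_add(g, "flatten", x, name = paste0("flatten_", s))
    }
    merged <- graph_add(g, "concat", c(ends$rgb, ends$flow), name = "late_fusion")
    out <- emit_fc_head(g, merged, sc(spec$fc_units), spec$n_classes,
                        activation = "relu", dropout = spec$dropout_rate)
  }
  list(graph = g, output_id = out, input_ids = ins,
       module_outputs = as.list(module_outputs))
}

build_crs <- function(spec) {
  g <- graph_new()
  sc <- function(w) .sc(w, spec$filter_scale)
  ins <- .inputs(g, spec)
  ws <- lapply(.hcn_crs_widths[[spec$variant]], sc)
  strides <- list(c(1L, 1L, 1L), c(2L, 2L, 2L), c(2L, 2L, 2L),
                  c(2L, 2L, 2L), c(1L, 2L, 2L))
  streams <- ins
  module_outputs <- integer(5)
  for (i in 1:5) {
    feeds <- if (i == 1L || spec$variant == "standalone") streams else {
      # cross reinforcement: each stream consumes the concatenation of both
      # streams' previous features
      comb <- graph_add(g, "concat", c(streams$rgb, streams$flow),
                        name = sprintf("m%d_cross", i))
      list(rgb = comb, flow = comb)
    }
    blocks <- lapply(names(streams), function(s)
      emit_inception_v1(g, feeds[[s]], ws[[i]], strides[[i]],
                        name = sprintf("m%d_%s", i, s)))
    names(blocks) <- names(streams)
    module_outputs[i] <- graph_add(g, "concat", c(blocks$rgb, blocks$flow),
                                   name = sprintf("m%d_out", i))
    streams <- blocks
  }
  pooled <- graph_add(g, "global_avg_pool", module_outputs[5], name = "gap")
  out <- emit_fc_head(g, pooled, sc(spec$fc_units), spec$n_classes,
                      activation = "relu", dropout = spec$dropout_rate)
  list(graph = g, output_id = out, input_ids = ins,
       module_outputs = as.list(module_outputs))
}

#' Class probabilities from a built model
#'
#' Runs the forward pass in inference mode and applies the softmax, so each
#' row of the result is the 8-way (or `n_classes`-way) class distribution of
#' one cuboid pair.
#'
#' @param model A built model with materialized weights.
#' @param rgb,flow Arrays `N x T x H x W x C` (a single `T x H x W x C`
#'   cuboid is promoted to a batch of one).
#' @return `N x n_classes` matrix of probabilities; rows sum to 1.
#' @export
predict_model <- function(model, rgb, flow) {
  rgb <- .as_batch(rgb); flow <- .as_batch(flow)
  if (!model_is_materialized(model)) materialize_params(model)
  logits <- graph_forward(model, list(rgb = rgb, flow = flow), training = FALSE)
  softmax(logits)
}

.as_batch <- function(x) {
  if (length(dim(x)) == 4L) dim(x) <- c(1L, dim(x))
  x
}
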