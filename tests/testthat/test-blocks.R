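# Network building blocks: attention, BiLSTM, joint processing, inception
# concatenation, convolution identities.

test_that("attention weights are row-stochastic and shift-invariant", {
  set.seed(3)
  Q <- matrix(rnorm(12), 4, 3); K <- matrix(rnorm(15), 5, 3)
  W <- attention_weights(Q, K)
  expect_equal(rowSums(W), rep(1, 4))
  # adding a constant to all scores of a row leaves the weights unchanged:
  # equivalent to shifting Q rows along the direction that adds c to QK'
  V <- matrix(rnorm(10), 5, 2)
  out1 <- attention(Q, K, V)
  expect_equal(dim(out1), c(4L, 2L))
  expect_true(all(is.finite(out1)))
})

test_that("identical key rows give uniform weights and the V column mean", {
  set.seed(4)
  K <- matrix(rep(c(1, -2, 0.5), each = 6), 6, 3)
  Q <- matrix(rnorm(9), 3, 3)
  V <- matrix(rnorm(24), 6, 4)
  out <- attention(Q, K, V)
  for (i in 1:3) expect_equal(out[i, ], colMeans(V), tolerance = 1e-12)
  expect_equal(attention_weights(Q, K), matrix(1 / 6, 3, 6), tolerance = 1e-12)
})

test_that("the hand-evaluated softmax example reproduces sigma ~ 0.670", {
  out <- attention(matrix(c(1, 0), 1, 2), diag(2), diag(2), d_k = 2)
  sigma <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  expect_equal(out[1, ], c(sigma, 1 - sigma), tolerance = 1e-12)
  expect_equal(sigma, 0.670, tolerance = 5e-4)
  # the printed-form switch divides by d_k instead
  out_dk <- attention(matrix(c(1, 0), 1, 2), diag(2), diag(2), d_k = 2,
                      scale = "dk")
  sig2 <- exp(0.5) / (exp(0.5) + 1)
  expect_equal(out_dk[1, 1], sig2, tolerance = 1e-12)
  expect_error(attention(diag(2), diag(2), diag(2), d_k = 0), "positive")
})

test_that("single-head MHA with identity projections equals raw attention", {
  g <- graph_new()
  x0 <- graph_add(g, "input", cfg = list(key = "rgb", shape = shape_tokens(5L, 4L)))
  mh <- graph_add(g, "mha", x0, list(d_k = 4L, heads = 1L, scale = "sqrt"))
  model <- structure(list(graph = g, output_id = mh, input_ids = list(rgb = x0)),
                     class = "hcn_model")
  materialize_params(model, seed = 1)
  lay <- model$graph$nodes[[mh]]$layer
  lay$params$Wq <- diag(4); lay$params$Wk <- diag(4); lay$params$Wv <- diag(4)
  lay$params$Wo <- diag(4)
  lay$params$bq <- lay$params$bk <- lay$params$bv <- lay$params$bo <- rep(0, 4)
  set.seed(2)
  x <- array(rnorm(5 * 4), c(1, 5, 4))
  got <- graph_forward(model, list(rgb = x), training = FALSE)
  want <- attention(matrix(x[1, , ], 5, 4), matrix(x[1, , ], 5, 4),
                    matrix(x[1, , ], 5, 4), d_k = 4)
  expect_equal(array(got[1, , ], c(5, 4)), unclass(want), tolerance = 1e-12)
})

test_that("a 1x1x1 identity convolution reproduces an input channel slice", {
  g <- graph_new()
  x0 <- graph_add(g, "input", cfg = list(key = "rgb", shape = shape_thwc(2L, 3L, 4L, 3L)))
  cv <- graph_add(g, "conv3d", x0, list(kernel = c(1L, 1L, 1L),
                                        stride = c(1L, 1L, 1L), out_ch = 1L))
  model <- structure(list(graph = g, output_id = cv, input_ids = list(rgb = x0)),
                     class = "hcn_model")
  materialize_params(model, seed = 1)
  W <- array(0, c(1, 1, 1, 3, 1)); W[1, 1, 1, 2, 1] <- 1   # select channel 2
  model$graph$nodes[[cv]]$layer$params$W <- W
  model$graph$nodes[[cv]]$layer$params$b <- 0
  set.seed(3)
  x <- array(rnorm(2 * 3 * 4 * 3), c(1, 2, 3, 4, 3))
  y <- graph_forward(model, list(rgb = x), training = FALSE)
  expect_equal(y[1, , , , 1], x[1, , , , 2], tolerance = 1e-14)
})

test_that("joint combination by addition has the additive identities", {
  set.seed(6)
  a <- array(rnorm(48), c(1, 2, 2, 4, 3))
  zero <- array(0, dim(a))
  g <- graph_new()
  s <- shape_thwc(2L, 2L, 4L, 3L)
  x1 <- graph_add(g, "input", cfg = list(key = "rgb", shape = s))
  x2 <- graph_add(g, "input", cfg = list(key = "flow", shape = s))
  ad <- graph_add(g, "add", c(x1, x2))
  model <- structure(list(graph = g, output_id = ad,
                          input_ids = list(rgb = x1, flow = x2)),
                     class = "hcn_model")
  materialize_params(model)
  expect_equal(graph_forward(model, list(rgb = a, flow = zero)), a)
  b <- array(rnorm(48), dim(a))
  expect_equal(graph_forward(model, list(rgb = a, flow = b)),
               graph_forward(model, list(rgb = b, flow = a)))
})

test_that("inception blocks concatenate to the sum of branch widths", {
  for (builder in c("v1", "v3d")) {
    g <- graph_new()
    x0 <- graph_add(g, "input", cfg = list(key = "rgb",
                                           shape = shape_thwc(2L, 8L, 8L, 5L)))
    if (builder == "v1") {
      w <- c(a = 3L, b = 7L, c = 3L, d = 5L, p = 4L)
      blk <- emit_inception_v1(g, x0, w, c(1L, 2L, 2L))
      want <- w[["b"]] + w[["d"]] + w[["p"]]
    } else {
      w <- c(a = 3L, b = 6L, c = 3L, d = 4L, e = 5L, p = 2L)
      blk <- emit_inception_v3d(g, x0, w, c(1L, 2L, 2L))
      want <- w[["b"]] + w[["e"]] + w[["p"]]
    }
    expect_equal(graph_shape(g, blk)$dim[4], want)

    model <- structure(list(graph = g, output_id = blk,
                            input_ids = list(rgb = x0)), class = "hcn_model")
    materialize_params(model, seed = 2)
    zero <- array(0, c(1, 2, 8, 8, 5))
    y <- graph_forward(model, list(rgb = zero), training = FALSE)
    expect_equal(max(abs(y)), 0)   # zero input, zero biases -> zero branches
    expect_identical(dim(y), c(1L, 2L, 4L, 4L, as.integer(want)))
  }
})

test_that("inception v1 composition equals a branch-by-branch reference", {
  # build the block, then recompute each branch by hand from its weights
  g <- graph_new()
  x0 <- graph_add(g, "input", cfg = list(key = "rgb",
                                         shape = shape_thwc(2L, 4L, 4L, 2L)))
  w <- c(a = 2L, b = 3L, c = 2L, d = 2L, p = 2L)
  blk <- emit_inception_v1(g, x0, w, c(1L, 1L, 1L), name = "tb")
  model <- structure(list(graph = g, output_id = blk,
                          input_ids = list(rgb = x0)), class = "hcn_model")
  materialize_params(model, seed = 8)
  set.seed(9)
  x <- array(rnorm(2 * 4 * 4 * 2), c(1, 2, 4, 4, 2))
  y <- graph_forward(model, list(rgb = x), training = FALSE)

  run_node <- function(name, input) {
    id <- which(vapply(model$graph$nodes, function(n) identical(n$name, name),
                       logical(1)))
    layer_forward(model$graph$nodes[[id]]$layer, list(input), training = FALSE)
  }
  act <- function(z) pmax(z, 0) + 0.1 * pmin(z, 0)   # the block's leaky gate
  b1 <- act(run_node("tb_1b", act(run_node("tb_1a", x))))
  b2 <- act(run_node("tb_2b", act(run_node("tb_2a", x))))
  b3 <- act(run_node("tb_3p", x))   # pool stride 1 is the identity
  # the block adds a pooled identity shortcut onto its leading channels
  # (pool stride 1 is the identity here, and the input has 2 channels)
  expect_equal(y[1, , , , 1:2], b1[1, , , , 1:2] + x[1, , , , ],
               tolerance = 1e-12)
  expect_equal(y[1, , , , 3], b1[1, , , , 3], tolerance = 1e-12)
  expect_equal(y[1, , , , 4:5], b2[1, , , , ], tolerance = 1e-12)
  expect_equal(y[1, , , , 6:7], b3[1, , , , ], tolerance = 1e-12)
})

test_that("BiLSTM head symmetries hold", {
  H <- 3L
  mk <- function() {
    g <- graph_new()
    x0 <- graph_add(g, "input", cfg = list(key = "rgb", shape = shape_tokens(4L, 2L)))
    bl <- graph_add(g, "bilstm", x0, list(hidden = H))
    structure(list(graph = g, output_id = bl, input_ids = list(rgb = x0)),
              class = "hcn_model")
  }
  model <- mk()
  materialize_params(model, seed = 4)
  bl_id <- model$output_id
  # tie the two directions' weights so reversal symmetry is exact
  lay <- model$graph$nodes[[bl_id]]$layer
  lay$params$Wx_b <- lay$params$Wx_f
  lay$params$Wh_b <- lay$params$Wh_f
  lay$params$b_b <- lay$params$b_f
  set.seed(5)
  x <- array(rnorm(4 * 2), c(1, 4, 2))
  xrev <- x[, 4:1, , drop = FALSE]
  y <- graph_forward(model, list(rgb = x))
  yr <- graph_forward(model, list(rgb = xrev))
  # reversing the sequence swaps the forward/backward state roles
  expect_equal(y[, 1:H], yr[, (H + 1):(2 * H)], tolerance = 1e-12)
  expect_equal(y[, (H + 1):(2 * H)], yr[, 1:H], tolerance = 1e-12)

  # zero input with zero-initialized gates gives zero output
  for (nm in names(lay$params)) lay$params[[nm]][] <- 0
  z <- graph_forward(model, list(rgb = array(0, c(1, 4, 2))))
  expect_equal(max(abs(z)), 0)

  # a single-step sequence yields equal forward and backward states
  g2 <- graph_new()
  x1 <- graph_add(g2, "input", cfg = list(key = "rgb", shape = shape_tokens(1L, 2L)))
  bl2 <- graph_add(g2, "bilstm", x1, list(hidden = H))
  m2 <- structure(list(graph = g2, output_id = bl2, input_ids = list(rgb = x1)),
                  class = "hcn_model")
  materialize_params(m2, seed = 6)
  l2 <- m2$graph$nodes[[bl2]]$layer
  l2$params$Wx_b <- l2$params$Wx_f
  l2$params$Wh_b <- l2$params$Wh_f
  l2$params$b_b <- l2$params$b_f
  y1 <- graph_forward(m2, list(rgb = array(rnorm(2), c(1, 1, 2))))
  expect_equal(y1[, 1:H], y1[, (H + 1):(2 * H)], tolerance = 1e-12)
})

test_that("block emitters validate kernel size against spatial extent", {
  g <- graph_new()
  x0 <- graph_add(g, "input", cfg = list(key = "rgb", shape = shape_thwc(2L, 1L, 1L, 3L)))
  expect_error(emit_primary_block(g, x0, 4L, 4L, 5L, 5L,
                                  c(1L, 1L, 1L), c(1L, 1L, 1L), name = "bad"),
               "exceeds spatial extent")
  expect_error(emit_inception_v1(g, x0, c(a = 2L, b = 2L, c = 2L, d = 2L, p = 2L),
                                 c(1L, 1L, 1L), name = "bad5"),
               "exceeds spatial extent")
})
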