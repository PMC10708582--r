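# Architecture accounting against the published tables, shape fidelity and
# construction invariants.

published_params <- list(
  sharing = c(baseline = 11315848, civ3d_bilstm = 13243712,
              civ3d_mha = 15554112, srs = 9671872, crs = 22927824),
  standalone = c(baseline = 11348728, civ3d_bilstm = 16623752,
                 civ3d_mha = 19044744, srs = 9670024, crs = 22483944))

test_that("trainable parameter counts reproduce the published totals", {
  for (v in names(published_params)) {
    for (nm in names(published_params[[v]])) {
      m <- build_model(model_spec(nm, v))
      expect_identical(count_parameters(m),
                       unname(published_params[[v]][nm]),
                       label = sprintf("%s (%s) parameter count", nm, v))
    }
  }
})

test_that("the FLOPS figure is twice the MAC-bearing parameter count", {
  base <- build_model(model_spec("baseline"))
  expect_equal(round(count_flops(base) / 1e6, 2), 22.63)
  srs <- build_model(model_spec("srs"))
  expect_equal(round(count_flops(srs) / 1e6, 2), 19.34)
  # a dense layer 4 -> 2 with bias carries 10 parameters, 20 FLOPS
  g <- graph_new()
  x0 <- graph_add(g, "input", cfg = list(key = "rgb", shape = shape_vec(4L)))
  d <- graph_add(g, "dense", x0, list(units = 2L))
  toy <- structure(list(graph = g, output_id = d, input_ids = list(rgb = x0)),
                   class = "hcn_model")
  expect_equal(count_parameters(toy), 10)
  expect_equal(count_flops(toy), 20)
  # normalization parameters are excluded from the FLOPS figure
  expect_lt(count_flops(base), 2 * count_parameters(base))
  expect_equal(count_flops(srs), 2 * count_parameters(srs))  # SRS has no BN
})

published_shapes <- list(
  baseline = list(c(4, 24, 32, 24), c(2, 12, 16, 48), c(1, 6, 8, 96), c(1, 3, 4, 192)),
  civ3d_mha = list(c(4, 24, 32, 24), c(2, 12, 16, 48), c(1, 6, 8, 96), c(1, 3, 4, 192)),
  civ3d_bilstm = list(c(4, 24, 32, 24), c(2, 12, 16, 48), c(1, 6, 8, 96), c(1, 3, 4, 192)),
  srs = list(c(8, 96, 128, 72), c(4, 48, 64, 144), c(2, 24, 32, 288),
             c(1, 12, 16, 576), c(1, 6, 8, 576), c(1, 3, 4, 384)),
  crs = list(c(8, 96, 128, 72), c(4, 48, 64, 144), c(2, 24, 32, 288),
             c(1, 12, 16, 576), c(1, 6, 8, 1152)))

test_that("per-module output shapes match the published module tables", {
  for (nm in names(published_shapes)) {
    m <- build_model(model_spec(nm, "sharing"))
    got <- lapply(layer_output_shapes(m), as.numeric)
    expect_equal(got, published_shapes[[nm]], label = paste(nm, "module shapes"))
  }
})

test_that("a desk-scale forward pass realizes the symbolic shape trace", {
  spec <- desk_model_spec("baseline")
  m <- build_model(spec)
  materialize_params(m, seed = 1)
  set.seed(2)
  x <- array(runif(prod(desk_shape)), c(1L, desk_shape))
  invisible(graph_forward(m, list(rgb = x, flow = x), training = FALSE))
  for (i in seq_along(m$module_outputs)) {
    id <- m$module_outputs[[i]]
    expect_identical(dim(m$graph$values[[id]])[-1],
                     as.integer(m$graph$nodes[[id]]$shape$dim),
                     label = sprintf("module %d runtime shape", i))
  }
})

test_that("all ten variants produce finite softmax outputs summing to one", {
  set.seed(3)
  x <- array(runif(2 * prod(desk_shape)), c(2L, desk_shape))
  for (nm in c("baseline", "civ3d_mha", "civ3d_bilstm", "srs", "crs")) {
    shapes <- list()
    for (v in c("sharing", "standalone")) {
      m <- build_model(desk_model_spec(nm, v))
      materialize_params(m, seed = 4)
      p <- predict_model(m, x, x)
      expect_true(all(is.finite(p)), label = sprintf("%s %s finite", nm, v))
      expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
      shapes[[v]] <- dim(p)
    }
    # sharing and standalone accept identical inputs, identical output shape
    expect_identical(shapes$sharing, shapes$standalone)
  }
})

test_that("zeroing one stream of the CRS model still gives finite outputs", {
  m <- build_model(desk_model_spec("crs"))
  materialize_params(m, seed = 5)
  set.seed(6)
  x <- array(runif(prod(desk_shape)), c(1L, desk_shape))
  p <- predict_model(m, x, array(0, c(1L, desk_shape)))
  expect_true(all(is.finite(p)))
})

test_that("model construction is deterministic", {
  a <- build_model(model_spec("civ3d_mha"))
  b <- build_model(model_spec("civ3d_mha"))
  expect_identical(count_parameters(a), count_parameters(b))
  expect_identical(layer_output_shapes(a), layer_output_shapes(b))
})

test_that("the SRS temporal crop scales with T and leaves complexity fixed", {
  crop_of <- function(m) {
    id <- which(vapply(m$graph$nodes, function(n) n$type == "temporal_crop",
                       logical(1)))
    m$graph$nodes[[id]]$cfg[c("head", "tail")]
  }
  m8 <- build_model(model_spec("srs", input_shape = c(8L, 96L, 128L, 3L)))
  expect_equal(crop_of(m8), list(head = 2L, tail = 2L))
  m4 <- build_model(model_spec("srs", input_shape = c(4L, 96L, 128L, 3L)))
  expect_equal(crop_of(m4), list(head = 1L, tail = 1L))
  m16 <- build_model(model_spec("srs", input_shape = c(16L, 96L, 128L, 3L)))
  expect_equal(crop_of(m16), list(head = 4L, tail = 4L))
  # removing frames does not change the architecture's complexity
  expect_identical(count_parameters(m4), count_parameters(m8))
  expect_identical(count_parameters(m16), count_parameters(m8))
})

test_that("degenerate geometries raise build errors naming the module", {
  expect_error(build_model(model_spec("srs", input_shape = c(2L, 96L, 128L, 3L))),
               "crop")
  expect_error(build_model(model_spec("baseline", input_shape = c(8L, 8L, 8L, 3L))),
               "m3|m4")
})

test_that("the learning-rate defaults follow the per-architecture table", {
  expect_equal(model_spec("baseline")$learning_rate, 5e-4)
  for (nm in c("civ3d_mha", "civ3d_bilstm", "srs", "crs"))
    expect_equal(model_spec(nm)$learning_rate, 1e-3)
})
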