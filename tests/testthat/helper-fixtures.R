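# Shared fixtures, generated once per test session.

.fixture_env <- new.env(parent = emptyenv())

# desk-scale geometry used throughout the suite
desk_shape <- c(8L, 24L, 32L, 3L)

desk_synth_spec <- function(clips_per_class = 10L, seed = 11L, ...) {
  synthetic_spec(clips_per_class = clips_per_class, T = desk_shape[1],
                 H = desk_shape[2], W = desk_shape[3], seed = seed, ...)
}

# the 80-clip synthetic set (8 classes x 10 clips), built once
desk_split <- function() {
  if (is.null(.fixture_env$split))
    .fixture_env$split <- generate_dataset(desk_synth_spec())
  .fixture_env$split
}

desk_model_spec <- function(name, variant = "sharing", ...) {
  model_spec(name, variant, input_shape = desk_shape,
             filter_scale = 1 / 4, dropout_rate = 0, ...)
}

# smoke-test training configuration (desk-scale conditions)
desk_train_config <- function(...) {
  training_config(epochs = 30L, batch_size = 8L, learning_rate = 0.05,
                  warmup_epochs = 2L, clip_norm = 2,
                  plateau_patience = 5L, min_delta = 5e-3,
                  early_stop_patience = 40L,
                  target_train_acc = 0.95, max_seconds = 100, ...)
}

# tiny random cuboid list for store round-trips
random_cuboids <- function(n, t = 2L, h = 4L, w = 5L, c = 3L, seed = 1L,
                           labels = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    list(data = array(runif(t * h * w * c), c(t, h, w, c)),
         flow = array(runif(t * h * w * c), c(t, h, w, c)),
         label = labels[i] %||% sample(letters[1:4], 1),
         origin = list(source_id = sprintf("v%02d", i %% 5), start = i)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# constant-valued frame helper
const_frame <- function(h, w, vals = c(10, 20, 30)) {
  f <- array(0, c(h, w, length(vals)))
  for (cc in seq_along(vals)) f[, , cc] <- vals[cc]
  f
}
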