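# Synthetic home-cage clips with class-specific motion.
#
# Each clip renders a textured ellipsoidal "mouse" on a static cage-like
# background (vertical illumination gradient plus high-contrast bars, so
# dense flow is well-posed) and animates it with the kinematic signature of
# one of the eight ethogram behaviors. The generator is deterministic given
# its seed and produces matched RGB and optical-flow cuboids; it emulates
# class-discriminative motion statistics, not the photometric detail of
# real recordings.

.hcn_classes <- c("drink", "eat", "groom", "hang", "micromovement",
                  "rear", "rest", "walk")

#' Specification for the synthetic clip generator
#'
#' @param classes Behavior class names (default: the eight-behavior
#'   home-cage ethogram).
#' @param clips_per_class Clips generated per class.
#' @param T,H,W,C Cuboid geometry (defaults mirror the reference pipeline:
#'   8 frames of 96 x 128 RGB).
#' @param noise_sd Per-pixel Gaussian noise (intensity units on [0,255]).
#' @param imbalance Named multipliers; a class with factor `f` receives
#'   `clips_per_class / f` clips (rounded, at least 1).
#' @param seed Base seed; all generation derives deterministically from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(classes = .hcn_classes, clips_per_class = 10L,
                           T = 8L, H = 96L, W = 128L, C = 3L,
                           noise_sd = 2, imbalance = NULL, seed = 0L) {
  stopifnot(length(classes) >= 2, clips_per_class >= 1, T >= 2, C %in% c(1L, 3L))
  structure(list(classes = classes, clips_per_class = as.integer(clips_per_class),
                 T = as.integer(T), H = as.integer(H), W = as.integer(W),
                 C = as.integer(C), noise_sd = noise_sd,
                 imbalance = imbalance, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.clip_seed <- function(spec, class_idx, k) {
  as.integer((as.numeric(spec$seed) * 7919 + class_idx * 104729 + k * 131) %%
               2147483647)
}

.render_background <- function(H, W, seed) {
  set.seed(seed)
  grad <- matrix(rep(seq(60, 120, length.out = H), W), H, W)
  bars <- ((col(grad) + seed %% 7) %% max(6L, W %/% 8L)) < 2
  bg <- grad + 70 * bars
  bg + matrix(stats::rnorm(H * W, 0, 3), H, W)   # frozen texture
}

# Per-class kinematics; displacement values scale with frame width. Each
# behavior combines a characteristic cage location (spout, hopper, ceiling
# bars, open floor) with its motion signature, mirroring how the behaviors
# present in a real side-view cage.
.class_motion <- function(class, T, H, W, rng) {
  s <- W / 128
  t <- seq_len(T + 1L)
  at <- function(fy, fx) list(cx = rep(W * fx, T + 1), cy = rep(H * fy, T + 1),
                              ax = rep(W * 0.11, T + 1), ay = rep(H * 0.10, T + 1))
  jitter <- function(sd) stats::rnorm(T + 1, 0, sd * s)
  switch(class,
    rest = {                     # flattened, motionless, in the far corner
      out <- at(0.80, 0.75)
      out$ay <- out$ay * 0.6; out$ax <- out$ax * 1.25
      out
    },
    micromovement = {            # in place on the floor, sub-pixel jitter
      out <- at(0.70, 0.28)
      out$cx <- out$cx + jitter(0.35); out$cy <- out$cy + jitter(0.35)
      out
    },
    walk = {                     # linear translation across the floor
      out <- at(0.65, 0.5)
      dir <- if (stats::runif(1) < 0.5) 1 else -1
      out$cx <- out$cx - dir * 2 * s * (T / 2) + dir * 2 * s * t
      out
    },
    groom = {                    # stationary mid-cage, periodic deformation
      out <- at(0.62, 0.50)
      out$ax <- out$ax * (1 + 0.30 * sin(2 * pi * t / 3))
      out$ay <- out$ay * (1 - 0.20 * sin(2 * pi * t / 3))
      out
    },
    rear = {                     # vertical elongation, center rising
      out <- at(0.55, 0.38)
      gr <- seq(1, 1.9, length.out = T + 1)
      out$ay <- out$ay * gr; out$ax <- out$ax / sqrt(gr)
      out$cy <- out$cy - (out$ay / gr) * (gr - 1)
      out
    },
    hang = {                     # suspended from the ceiling bars, swinging
      out <- at(0.15, 0.50)
      out$cx <- out$cx + 1.2 * s * sin(2 * pi * t / 4)
      out
    },
    eat = {                      # at the food hopper (left wall), nibbling
      out <- at(0.50, 0.12)
      out$cx <- out$cx + 0.8 * s * sin(2 * pi * t / 2.5)
      out
    },
    drink = {                    # at the spout (upper right), head bobbing
      out <- at(0.30, 0.88)
      out$cy <- out$cy + 0.6 * s * sin(2 * pi * t / 2)
      out
    },
    stop("generate_clip: unknown class '", class, "'")
  )
}

.render_frames <- function(spec, motion, seed) {
  H <- spec$H; W <- spec$W; T <- spec$T
  bg <- .render_background(H, W, seed %% 997L + 1L)
  set.seed(seed)
  rows <- matrix(rep(seq_len(H), W), H, W)
  cols <- matrix(rep(seq_len(W), each = H), H, W)
  phase <- stats::runif(1, 0, 2 * pi)
  frames <- vector("list", T + 1L)
  for (t in seq_len(T + 1L)) {
    r2 <- ((cols - motion$cx[t]) / motion$ax[t])^2 +
          ((rows - motion$cy[t]) / motion$ay[t])^2
    w <- pmin(pmax(1.25 - r2, 0), 1)
    stripes <- 35 * sin(cols * 0.9 + rows * 0.35 + phase)
    body <- 185 + stripes
    f <- bg * (1 - w) + body * w
    f <- f + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    f <- pmin(pmax(f, 0), 255)
    if (spec$C == 3L) {
      fr <- array(0, c(H, W, 3L))
      fr[, , 1] <- f; fr[, , 2] <- f * 0.96; fr[, , 3] <- f * 0.88
      frames[[t]] <- fr
    } else {
      frames[[t]] <- array(f, c(H, W, 1L))
    }
  }
  frames
}

#' Generate one labeled synthetic clip (RGB + flow cuboids)
#'
#' @param class_name One of the spec's behavior classes.
#' @param spec A [synthetic_spec()].
#' @param seed Clip seed (deterministic output for a given
#'   `(class_name, seed)`).
#' @return List with `data` (RGB cuboid, `T x H x W x C` in `[0, 1]`),
#'   `flow` (matched flow cuboid), `label` (class name) and `origin`.
#' @export
generate_clip <- function(class_name, spec, seed = 0L) {
  if (!class_name %in% spec$classes)
    stop("generate_clip: unknown class '", class_name, "'")
  set.seed(seed)
  motion <- .class_motion(class_name, spec$T, spec$H, spec$W, NULL)
  frames <- .render_frames(spec, motion, seed)
  sq <- frame_sequence(frames, source_id = sprintf("synthetic_%s_%d", class_name, seed))
  # displacements scale with the raster, so the encoding's full-scale
  # magnitude follows the frame width (8 px at the reference W = 128)
  flows <- compute_flow_stream(sq, mag_scale = 8 * spec$W / 128)
  T <- spec$T
  rgb <- array(0, c(T, spec$H, spec$W, spec$C))
  flw <- array(0, c(T, spec$H, spec$W, 3L))
  for (t in seq_len(T)) {
    rgb[t, , , ] <- frames[[t]] / 255
    flw[t, , , ] <- flows[[t]]$frame / 255
  }
  list(data = rgb, flow = flw, label = class_name,
       origin = list(source_id = sq$source_id, start = 0L),
       flow_fields = lapply(flows, function(f) f[c("dx", "dy")]))
}

#' Generate a stratified synthetic dataset split
#'
#' Produces `clips_per_class` clips per class (adjusted by the imbalance
#' factors) and splits them 70/15/15 into train/validation/test within each
#' class.
#'
#' @param spec A [synthetic_spec()].
#' @param progress Print one line per class while generating.
#' @return A [dataset_split()]; cuboids carry both `data` (RGB) and `flow`.
#' @export
generate_dataset <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  train <- list(); validation <- list(); test <- list()
  for (ci in seq_along(spec$classes)) {
    cl <- spec$classes[ci]
    f <- if (!is.null(spec$imbalance) && cl %in% names(spec$imbalance))
      spec$imbalance[[cl]] else 1
    n <- max(1L, as.integer(round(spec$clips_per_class / f)))
    if (progress) message("generating ", n, " '", cl, "' clips")
    clips <- lapply(seq_len(n), function(k)
      generate_clip(cl, spec, .clip_seed(spec, ci, k)))
    n_tr <- max(1L, floor(0.7 * n))
    n_va <- floor(0.15 * n)
    train <- c(train, clips[seq_len(n_tr)])
    if (n_va > 0) validation <- c(validation, clips[n_tr + seq_len(n_va)])
    if (n - n_tr - n_va > 0) test <- c(test, clips[(n_tr + n_va + 1L):n])
  }
  dataset_split(train, validation, test)
}
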