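# Layer primitives for the spatiotemporal network engine.
#
# Activations move through the graph as dense R arrays in N x T x H x W x C
# layout ("thwc"), as token sequences N x S x D ("tokens"), or as per-sample
# feature matrices N x F ("vec"). Every layer implements shape inference,
# parameter-shape declaration, a forward pass and a backward pass; parameter
# gradients accumulate in the layer environment so a plain SGD step can
# follow. Convolutions use "same" padding with ceil(in/stride) output sizes.

shape_thwc <- function(t, h, w, c) list(kind = "thwc", dim = c(t, h, w, c))
shape_tokens <- function(s, d) list(kind = "tokens", dim = c(s, d))
shape_vec <- function(f) list(kind = "vec", dim = f)

.last_dim <- function(shape) shape$dim[length(shape$dim)]

new_layer <- function(type, cfg = list()) {
  lay <- new.env(parent = emptyenv())
  lay$type <- type
  lay$cfg <- cfg
  lay$params <- NULL
  lay$grads <- NULL
  lay$cache <- NULL
  lay$state <- NULL    # running stats for batch norm
  lay
}

#' @noRd
layer_param_shapes <- function(type, cfg, in_shapes) {
  s1 <- in_shapes[[1]]
  switch(type,
    conv3d = {
      cin <- .last_dim(s1)
      list(W = c(cfg$kernel, cin, cfg$out_ch), b = cfg$out_ch)
    },
    dense = {
      cin <- .last_dim(s1)
      ps <- list(W = c(cin, cfg$units))
      if (isTRUE(cfg$bias) || is.null(cfg$bias)) ps$b <- cfg$units
      ps
    },
    batchnorm = {
      c_ <- .last_dim(s1)
      list(gamma = c_, beta = c_)
    },
    mha = {
      d <- .last_dim(s1)
      dk <- cfg$d_k; h <- cfg$heads
      list(Wq = c(d, h * dk), bq = h * dk,
           Wk = c(d, h * dk), bk = h * dk,
           Wv = c(d, h * dk), bv = h * dk,
           Wo = c(h * dk, d), bo = d)
    },
    bilstm = {
      d <- .last_dim(s1); H <- cfg$hidden
      list(Wx_f = c(d, 4 * H), Wh_f = c(H, 4 * H), b_f = 4 * H,
           Wx_b = c(d, 4 * H), Wh_b = c(H, 4 * H), b_b = 4 * H)
    },
    list()
  )
}

#' @noRd
layer_out_shape <- function(type, cfg, in_shapes) {
  s1 <- in_shapes[[1]]
  switch(type,
    input = s1,
    conv3d = {
      d <- ceiling(s1$dim[1:3] / cfg$stride)
      shape_thwc(d[1], d[2], d[3], cfg$out_ch)
    },
    maxpool3d = {
      d <- ceiling(s1$dim[1:3] / cfg$stride)
      shape_thwc(d[1], d[2], d[3], s1$dim[4])
    },
    dense = { s <- s1; s$dim[length(s$dim)] <- cfg$units; s },
    batchnorm = s1,
    leaky_relu = s1,
    dropout = s1,
    add = s1,
    pad_residual = s1,
    concat = {
      s <- s1
      s$dim[length(s$dim)] <- sum(vapply(in_shapes, .last_dim, numeric(1)))
      s
    },
    temporal_crop = {
      s <- s1
      s$dim[1] <- s$dim[1] - cfg$head - cfg$tail
      s
    },
    flatten = shape_vec(prod(s1$dim)),
    to_tokens = shape_tokens(prod(s1$dim[1:3]), s1$dim[4]),
    from_tokens = shape_thwc(cfg$t, cfg$h, cfg$w, s1$dim[2]),
    global_avg_pool = shape_vec(s1$dim[4]),
    mha = s1,
    bilstm = shape_vec(2 * cfg$hidden),
    stop("unknown layer type: ", type)
  )
}

# ---------------------------------------------------------------- helpers --

.init_uniform <- function(dims, limit) {
  array(stats::runif(prod(dims), -limit, limit), dim = if (length(dims) > 1) dims else NULL)
}

#' @noRd
layer_init_params <- function(lay, in_shapes) {
  ps <- layer_param_shapes(lay$type, lay$cfg, in_shapes)
  if (!length(ps)) {
    lay$params <- list()
    return(invisible(lay))
  }
  params <- list()
  for (nm in names(ps)) {
    d <- ps[[nm]]
    if (lay$type == "batchnorm") {
      params[[nm]] <- if (nm == "gamma") rep(1, d) else rep(0, d)
    } else if (length(d) == 1L) {
      params[[nm]] <- rep(0, d)   # biases start at zero
    } else {
      fan_in <- prod(d[-length(d)])
      fan_out <- d[length(d)]
      limit <- if (lay$type == "conv3d") sqrt(6 / fan_in) else sqrt(6 / (fan_in + fan_out))
      params[[nm]] <- .init_uniform(d, limit)
    }
  }
  if (lay$type == "bilstm") {
    H <- lay$cfg$hidden
    for (nm in c("b_f", "b_b")) params[[nm]][(H + 1):(2 * H)] <- 1  # forget-gate bias
  }
  if (lay$type == "batchnorm") {
    lay$state <- list(mean = rep(0, ps$gamma), var = rep(1, ps$gamma))
  }
  lay$params <- params
  lay$grads <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  invisible(lay)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.zero_grads <- function(lay) {
  if (length(lay$params))
    lay$grads <- lapply(lay$params, function(p) array(0, dim = dim(p) %||% length(p)))
}

# Same-padding geometry shared by conv and pool.
.pad_geom <- function(in_d, k, s) {
  out_d <- as.integer(ceiling(in_d / s))
  pad <- pmax((out_d - 1L) * s + k - in_d, 0L)
  list(out = out_d, before = pad %/% 2L, total = pad)
}

.offset_idx <- function(off, stride, n_out, pad_before) {
  # 1-based indices into the padded array for one kernel offset
  off + stride * (seq_len(n_out) - 1L)
}

# ---------------------------------------------------------------- conv3d --

# im2col via linear-index gather. Column order: block o + nk * (cin - 1)
# for kernel offset o (i1 fastest), matching matrix(W, nk * cin, cout) row
# order. Index arithmetic: element (n, t, h, w, c) of the padded array sits
# at n + N(t-1) + N T1 (h-1) + N T1 H1 (w-1) + N T1 H1 W1 (c-1); with
# t = i1 + s1 (to - 1) this splits into an output-position part and a
# kernel-offset/channel part, so one outer() builds the whole gather index.
# Index matrix mapping im2col elements to 0-based positions in the
# *unpadded* input (-1 marks same-padding positions). Rows run over
# (batch, to, ho, wo); columns over kernel offset (i1 fastest) then input
# channel, matching matrix(W, nk * cin, cout) row order.
.conv3d_geom <- function(dims, k, s, g) {
  n <- as.integer(dims[1])
  T_ <- as.integer(dims[2]); H_ <- as.integer(dims[3]); W_ <- as.integer(dims[4])
  cin <- as.integer(dims[5])
  str <- c(n, n * T_, n * T_ * H_, n * T_ * H_ * W_)
  dimpart <- function(kk, ss, out, size, before, stride) {
    # matrix [k x out]: (pos - 1) * stride-in-linear-units, NA if padded
    pos <- outer(seq_len(kk), ss * (seq_len(out) - 1L),
                 function(i, o) i + o - before)   # 1-based input coordinate
    val <- (pos - 1L) * stride
    val[pos < 1L | pos > size] <- NA_integer_
    val
  }
  tp <- dimpart(k[1], s[1], g$out[1], T_, g$before[1], str[1])
  hp <- dimpart(k[2], s[2], g$out[2], H_, g$before[2], str[2])
  wp <- dimpart(k[3], s[3], g$out[3], W_, g$before[3], str[3])
  nr <- n * prod(g$out)
  nk <- prod(k)
  base <- matrix(NA_integer_, nr, nk)
  o <- 0L
  for (i3 in seq_len(k[3])) for (i2 in seq_len(k[2])) for (i1 in seq_len(k[1])) {
    o <- o + 1L
    base[, o] <- (seq_len(n) - 1L) +
      rep(tp[i1, ], each = n) +
      rep(hp[i2, ], each = n * g$out[1]) +
      rep(wp[i3, ], each = n * g$out[1] * g$out[2])
  }
  chan <- str[4] * (seq_len(cin) - 1L)
  idx <- matrix(NA_integer_, nr, nk * cin)
  for (cc in seq_len(cin)) idx[, (cc - 1L) * nk + seq_len(nk)] <- base + chan[cc]
  idx[is.na(idx)] <- -1L
  list(idx = idx, n_in = prod(dims))
}

.conv3d_fw <- function(lay, x, training) {
  cfg <- lay$cfg
  k <- cfg$kernel; s <- cfg$stride
  dims <- dim(x)
  g <- .pad_geom(dims[2:4], k, s)
  key <- paste(dims, collapse = "x")
  if (is.null(lay$icache) || !identical(lay$icache$key, key)) {
    lay$icache <- c(list(key = key), .conv3d_geom(dims, k, s, g))
  }
  geo <- lay$icache
  cout <- cfg$out_ch
  nr <- dims[1] * prod(g$out)
  M <- hcn_gather(x, geo$idx, nr, ncol(geo$idx))
  Wm <- matrix(lay$params$W, ncol(geo$idx), cout)
  Ym <- M %*% Wm
  Ym <- Ym + rep(lay$params$b, each = nr)
  # cache the (shared) input rather than the im2col matrix: the gather is
  # cheap to redo in the backward pass and the matrix dominates peak memory
  lay$cache <- list(x = x, g = g, dims = dims)
  array(Ym, c(dims[1], g$out, cout))
}

.conv3d_bw <- function(lay, dy) {
  cfg <- lay$cfg
  ca <- lay$cache
  dims <- ca$dims; geo <- lay$icache
  cout <- cfg$out_ch
  dYm <- matrix(dy, ncol = cout)
  Wm <- matrix(lay$params$W, ncol(geo$idx), cout)
  M <- hcn_gather(ca$x, geo$idx, nrow(geo$idx), ncol(geo$idx))
  dWm <- crossprod(M, dYm)
  lay$grads$W <- lay$grads$W + array(dWm, dim(lay$params$W))
  lay$grads$b <- lay$grads$b + colSums(dYm)
  dM <- dYm %*% t(Wm)
  dX <- hcn_scatter_add(dM, geo$idx, geo$n_in)
  array(dX, dims)
}

# ---------------------------------------------------------------- pooling --

.maxpool_fw <- function(lay, x, training) {
  s <- lay$cfg$stride
  dims <- dim(x)
  n <- dims[1]; c_ <- dims[5]
  g <- .pad_geom(dims[2:4], s, s)   # window == stride
  pd <- dims[2:4] + g$total
  xp <- array(-Inf, c(n, pd, c_))
  xp[, g$before[1] + seq_len(dims[2]), g$before[2] + seq_len(dims[3]),
     g$before[3] + seq_len(dims[4]), ] <- x
  nr <- n * prod(g$out)
  best <- matrix(-Inf, nr, c_)
  which_off <- matrix(0L, nr, c_)
  off_id <- 0L
  for (i3 in seq_len(s[3])) for (i2 in seq_len(s[2])) for (i1 in seq_len(s[1])) {
    off_id <- off_id + 1L
    slab <- matrix(xp[, .offset_idx(i1, s[1], g$out[1]),
                       .offset_idx(i2, s[2], g$out[2]),
                       .offset_idx(i3, s[3], g$out[3]), , drop = FALSE], ncol = c_)
    upd <- slab > best
    best[upd] <- slab[upd]
    which_off[upd] <- off_id
  }
  lay$cache <- list(which = which_off, g = g, dims = dims, pd = pd)
  array(best, c(n, g$out, c_))
}

.maxpool_bw <- function(lay, dy) {
  s <- lay$cfg$stride
  ca <- lay$cache
  dims <- ca$dims; g <- ca$g
  n <- dims[1]; c_ <- dims[5]
  dYm <- matrix(dy, ncol = c_)
  dXp <- array(0, c(n, ca$pd, c_))
  off_id <- 0L
  for (i3 in seq_len(s[3])) for (i2 in seq_len(s[2])) for (i1 in seq_len(s[1])) {
    off_id <- off_id + 1L
    contrib <- dYm * (ca$which == off_id)
    ti <- .offset_idx(i1, s[1], g$out[1])
    hi <- .offset_idx(i2, s[2], g$out[2])
    wi <- .offset_idx(i3, s[3], g$out[3])
    dXp[, ti, hi, wi, ] <- dXp[, ti, hi, wi, , drop = FALSE] +
      array(contrib, c(n, g$out, c_))
  }
  dXp[, g$before[1] + seq_len(dims[2]), g$before[2] + seq_len(dims[3]),
      g$before[3] + seq_len(dims[4]), , drop = FALSE]
}

# ------------------------------------------------------------- pointwise --

.dense_fw <- function(lay, x, training) {
  d <- dim(x); cin <- d[length(d)]
  xm <- matrix(x, ncol = cin)
  ym <- xm %*% lay$params$W
  if (!is.null(lay$params$b)) ym <- ym + rep(lay$params$b, each = nrow(ym))
  lay$cache <- list(xm = xm, d = d)
  d[length(d)] <- lay$cfg$units
  array(ym, d)
}

.dense_bw <- function(lay, dy) {
  ca <- lay$cache
  dYm <- matrix(dy, ncol = lay$cfg$units)
  lay$grads$W <- lay$grads$W + crossprod(ca$xm, dYm)
  if (!is.null(lay$params$b)) lay$grads$b <- lay$grads$b + colSums(dYm)
  array(dYm %*% t(lay$params$W), ca$d)
}

.bn_fw <- function(lay, x, training) {
  d <- dim(x); c_ <- d[length(d)]
  xm <- matrix(x, ncol = c_)
  eps <- 1e-5
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = nrow(xm))
    v <- colMeans(xc * xc)
    mom <- 0.9
    lay$state$mean <- mom * lay$state$mean + (1 - mom) * mu
    lay$state$var <- mom * lay$state$var + (1 - mom) * v
  } else {
    mu <- lay$state$mean; v <- lay$state$var
    xc <- xm - rep(mu, each = nrow(xm))
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = nrow(xm))
  ym <- xhat * rep(lay$params$gamma, each = nrow(xm)) +
    rep(lay$params$beta, each = nrow(xm))
  lay$cache <- list(xhat = xhat, inv = inv, d = d, training = training)
  array(ym, d)
}

.bn_bw <- function(lay, dy) {
  ca <- lay$cache
  c_ <- length(lay$params$gamma)
  dYm <- matrix(dy, ncol = c_)
  m <- nrow(dYm)
  lay$grads$gamma <- lay$grads$gamma + colSums(dYm * ca$xhat)
  lay$grads$beta <- lay$grads$beta + colSums(dYm)
  g <- rep(lay$params$gamma, each = m)
  dxhat <- dYm * g
  if (isTRUE(ca$training)) {
    dxm <- (dxhat - rep(colMeans(dxhat), each = m) -
            ca$xhat * rep(colMeans(dxhat * ca$xhat), each = m)) *
      rep(ca$inv, each = m)
  } else {
    dxm <- dxhat * rep(ca$inv, each = m)
  }
  array(dxm, ca$d)
}

.lrelu_fw <- function(lay, x, training) {
  a <- lay$cfg$alpha %||% 0.1
  pos <- x >= 0
  lay$cache <- pos
  if (a == 0) return(x * pos)
  x * (pos + a * !pos)
}

.lrelu_bw <- function(lay, dy) {
  a <- lay$cfg$alpha %||% 0.1
  if (a == 0) return(dy * lay$cache)
  dy * (lay$cache + a * !lay$cache)
}

.dropout_fw <- function(lay, x, training) {
  rate <- lay$cfg$rate
  if (!training || rate <= 0) {
    lay$cache <- NULL
    return(x)
  }
  mask <- array(stats::runif(length(x)) >= rate, dim = dim(x)) / (1 - rate)
  lay$cache <- mask
  x * mask
}

.dropout_bw <- function(lay, dy) {
  if (is.null(lay$cache)) dy else dy * lay$cache
}

# --------------------------------------------------------------- reshape --

.flatten_fw <- function(lay, x, training) {
  d <- dim(x)
  lay$cache <- d
  matrix(x, nrow = d[1])
}

.flatten_bw <- function(lay, dy) array(dy, lay$cache)

.tokens_fw <- function(lay, x, training) {
  d <- dim(x)
  lay$cache <- d
  array(x, c(d[1], prod(d[2:4]), d[5]))
}

.tokens_bw <- function(lay, dy) array(dy, lay$cache)

.untokens_fw <- function(lay, x, training) {
  d <- dim(x)
  lay$cache <- d
  array(x, c(d[1], lay$cfg$t, lay$cfg$h, lay$cfg$w, d[3]))
}

.untokens_bw <- function(lay, dy) array(dy, lay$cache)

.gap_fw <- function(lay, x, training) {
  d <- dim(x)
  lay$cache <- d
  x3 <- array(x, c(d[1], prod(d[2:4]), d[5]))
  m <- prod(d[2:4])
  y <- matrix(0, d[1], d[5])
  for (cc in seq_len(d[5])) y[, cc] <- rowMeans(x3[, , cc, drop = FALSE])
  y
}

.gap_bw <- function(lay, dy) {
  d <- lay$cache
  m <- prod(d[2:4])
  dx3 <- array(0, c(d[1], m, d[5]))
  for (cc in seq_len(d[5])) dx3[, , cc] <- dy[, cc] / m
  array(dx3, d)
}

.crop_fw <- function(lay, x, training) {
  d <- dim(x)
  lay$cache <- d
  keep <- (lay$cfg$head + 1):(d[2] - lay$cfg$tail)
  x[, keep, , , , drop = FALSE]
}

.crop_bw <- function(lay, dy) {
  d <- lay$cache
  dx <- array(0, d)
  keep <- (lay$cfg$head + 1):(d[2] - lay$cfg$tail)
  dx[, keep, , , ] <- dy
  dx
}

# ------------------------------------------------------------- attention --

.softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

.mha_fw <- function(lay, x, training) {
  cfg <- lay$cfg
  d <- dim(x); n <- d[1]; S <- d[2]; dm <- d[3]
  h <- cfg$heads; dk <- cfg$d_k
  sc <- if (identical(cfg$scale, "dk")) cfg$d_k else sqrt(cfg$d_k)
  xm <- matrix(x, ncol = dm)
  P <- lay$params
  Q <- xm %*% P$Wq + rep(P$bq, each = n * S)
  K <- xm %*% P$Wk + rep(P$bk, each = n * S)
  V <- xm %*% P$Wv + rep(P$bv, each = n * S)
  heads <- matrix(0, n * S, h * dk)
  A_all <- vector("list", n * h)
  for (b in seq_len(n)) {
    rows <- seq(b, n * S, by = n)
    for (i in seq_len(h)) {
      cols <- ((i - 1) * dk + 1):(i * dk)
      A <- .softmax_rows(Q[rows, cols, drop = FALSE] %*%
                           t(K[rows, cols, drop = FALSE]) / sc)
      A_all[[(b - 1) * h + i]] <- A
      heads[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
  }
  y <- heads %*% P$Wo + rep(P$bo, each = n * S)
  lay$cache <- list(xm = xm, Q = Q, K = K, V = V, heads = heads, A = A_all,
                    n = n, S = S, dm = dm, sc = sc)
  array(y, d)
}

.mha_bw <- function(lay, dy) {
  cfg <- lay$cfg; ca <- lay$cache
  n <- ca$n; S <- ca$S; dm <- ca$dm
  h <- cfg$heads; dk <- cfg$d_k; sc <- ca$sc
  P <- lay$params
  dYm <- matrix(dy, ncol = dm)
  lay$grads$Wo <- lay$grads$Wo + crossprod(ca$heads, dYm)
  lay$grads$bo <- lay$grads$bo + colSums(dYm)
  dheads <- dYm %*% t(P$Wo)
  dQ <- matrix(0, n * S, h * dk)
  dK <- matrix(0, n * S, h * dk)
  dV <- matrix(0, n * S, h * dk)
  for (b in seq_len(n)) {
    rows <- seq(b, n * S, by = n)
    for (i in seq_len(h)) {
      cols <- ((i - 1) * dk + 1):(i * dk)
      A <- ca$A[[(b - 1) * h + i]]
      dH <- dheads[rows, cols, drop = FALSE]
      Vb <- ca$V[rows, cols, drop = FALSE]
      dA <- dH %*% t(Vb)
      dV[rows, cols] <- crossprod(A, dH)
      dscore <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dscore %*% ca$K[rows, cols, drop = FALSE] / sc
      dK[rows, cols] <- crossprod(dscore, ca$Q[rows, cols, drop = FALSE]) / sc
    }
  }
  lay$grads$Wq <- lay$grads$Wq + crossprod(ca$xm, dQ)
  lay$grads$bq <- lay$grads$bq + colSums(dQ)
  lay$grads$Wk <- lay$grads$Wk + crossprod(ca$xm, dK)
  lay$grads$bk <- lay$grads$bk + colSums(dK)
  lay$grads$Wv <- lay$grads$Wv + crossprod(ca$xm, dV)
  lay$grads$bv <- lay$grads$bv + colSums(dV)
  dxm <- dQ %*% t(P$Wq) + dK %*% t(P$Wk) + dV %*% t(P$Wv)
  array(dxm, c(n, S, dm))
}

# ---------------------------------------------------------------- bilstm --

.sigm <- function(z) 1 / (1 + exp(-z))

.lstm_dir_fw <- function(x, Wx, Wh, b, reverse) {
  d <- dim(x); n <- d[1]; S <- d[2]
  H <- nrow(Wh)
  steps <- if (reverse) rev(seq_len(S)) else seq_len(S)
  hprev <- matrix(0, n, H); cprev <- matrix(0, n, H)
  cache <- vector("list", S)
  for (si in seq_along(steps)) {
    t <- steps[si]
    xt <- matrix(x[, t, , drop = FALSE], nrow = n)
    z <- xt %*% Wx + hprev %*% Wh + rep(b, each = n)
    ig <- .sigm(z[, 1:H, drop = FALSE])
    fg <- .sigm(z[, (H + 1):(2 * H), drop = FALSE])
    og <- .sigm(z[, (2 * H + 1):(3 * H), drop = FALSE])
    gg <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    ct <- fg * cprev + ig * gg
    tc <- tanh(ct)
    ht <- og * tc
    cache[[si]] <- list(xt = xt, hprev = hprev, cprev = cprev,
                        i = ig, f = fg, o = og, g = gg, c = ct, tc = tc)
    hprev <- ht; cprev <- ct
  }
  list(h = hprev, cache = cache, steps = steps, H = H, n = n, S = S)
}

.lstm_dir_bw <- function(fwres, dh_final, x, Wx, Wh) {
  n <- fwres$n; S <- fwres$S; H <- fwres$H
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- rep(0, 4 * H)
  dx <- array(0, dim(x))
  dh <- dh_final; dc <- matrix(0, n, H)
  for (si in rev(seq_len(S))) {
    ca <- fwres$cache[[si]]
    t <- fwres$steps[si]
    do_ <- dh * ca$tc
    dct <- dc + dh * ca$o * (1 - ca$tc^2)
    di <- dct * ca$g
    df <- dct * ca$cprev
    dg <- dct * ca$i
    dzi <- di * ca$i * (1 - ca$i)
    dzf <- df * ca$f * (1 - ca$f)
    dzo <- do_ * ca$o * (1 - ca$o)
    dzg <- dg * (1 - ca$g^2)
    dz <- cbind(dzi, dzf, dzo, dzg)
    dWx <- dWx + crossprod(ca$xt, dz)
    dWh <- dWh + crossprod(ca$hprev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- matrix(dx[, t, , drop = FALSE], nrow = n) + dz %*% t(Wx)
    dh <- dz %*% t(Wh)
    dc <- dct * ca$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

.bilstm_fw <- function(lay, x, training) {
  P <- lay$params
  fw <- .lstm_dir_fw(x, P$Wx_f, P$Wh_f, P$b_f, reverse = FALSE)
  bw <- .lstm_dir_fw(x, P$Wx_b, P$Wh_b, P$b_b, reverse = TRUE)
  lay$cache <- list(fw = fw, bw = bw, x = x)
  cbind(fw$h, bw$h)
}

.bilstm_bw <- function(lay, dy) {
  ca <- lay$cache; P <- lay$params
  H <- lay$cfg$hidden
  rf <- .lstm_dir_bw(ca$fw, dy[, 1:H, drop = FALSE], ca$x, P$Wx_f, P$Wh_f)
  rb <- .lstm_dir_bw(ca$bw, dy[, (H + 1):(2 * H), drop = FALSE], ca$x, P$Wx_b, P$Wh_b)
  lay$grads$Wx_f <- lay$grads$Wx_f + rf$dWx
  lay$grads$Wh_f <- lay$grads$Wh_f + rf$dWh
  lay$grads$b_f <- lay$grads$b_f + rf$db
  lay$grads$Wx_b <- lay$grads$Wx_b + rb$dWx
  lay$grads$Wh_b <- lay$grads$Wh_b + rb$dWh
  lay$grads$b_b <- lay$grads$b_b + rb$db
  rf$dx + rb$dx
}

# ------------------------------------------------------------ dispatchers --

#' @noRd
layer_forward <- function(lay, inputs, training = FALSE) {
  x <- inputs[[1]]
  switch(lay$type,
    input = x,
    conv3d = .conv3d_fw(lay, x, training),
    maxpool3d = .maxpool_fw(lay, x, training),
    dense = .dense_fw(lay, x, training),
    batchnorm = .bn_fw(lay, x, training),
    leaky_relu = .lrelu_fw(lay, x, training),
    dropout = .dropout_fw(lay, x, training),
    add = Reduce(`+`, inputs),
    pad_residual = .padres_fw(lay, inputs),
    concat = {
      lay$cache <- vapply(inputs, function(z) dim(z)[length(dim(z))], numeric(1))
      nd <- length(dim(x))
      do.call(abind_last, inputs)
    },
    temporal_crop = .crop_fw(lay, x, training),
    flatten = .flatten_fw(lay, x, training),
    to_tokens = .tokens_fw(lay, x, training),
    from_tokens = .untokens_fw(lay, x, training),
    global_avg_pool = .gap_fw(lay, x, training),
    mha = .mha_fw(lay, x, training),
    bilstm = .bilstm_fw(lay, x, training),
    stop("unknown layer type: ", lay$type)
  )
}

#' @noRd
layer_backward <- function(lay, dy, n_inputs = 1L) {
  switch(lay$type,
    input = list(dy),
    conv3d = list(.conv3d_bw(lay, dy)),
    maxpool3d = list(.maxpool_bw(lay, dy)),
    dense = list(.dense_bw(lay, dy)),
    batchnorm = list(.bn_bw(lay, dy)),
    leaky_relu = list(.lrelu_bw(lay, dy)),
    dropout = list(.dropout_bw(lay, dy)),
    add = rep(list(dy), n_inputs),
    pad_residual = .padres_bw(lay, dy),
    concat = {
      sizes <- lay$cache
      nd <- length(dim(dy))
      out <- vector("list", length(sizes))
      at <- 0
      for (i in seq_along(sizes)) {
        idx <- (at + 1):(at + sizes[i])
        out[[i]] <- slice_last(dy, idx)
        at <- at + sizes[i]
      }
      out
    },
    temporal_crop = list(.crop_bw(lay, dy)),
    flatten = list(.flatten_bw(lay, dy)),
    to_tokens = list(.tokens_bw(lay, dy)),
    from_tokens = list(.untokens_bw(lay, dy)),
    global_avg_pool = list(.gap_bw(lay, dy)),
    mha = list(.mha_bw(lay, dy)),
    bilstm = list(.bilstm_bw(lay, dy)),
    stop("unknown layer type: ", lay$type)
  )
}

# channel-axis (last-dimension) concatenation / slicing for 2- to 5-D arrays
abind_last <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  nd <- length(d)
  cs <- vapply(xs, function(z) dim(z)[nd], numeric(1))
  out_d <- d; out_d[nd] <- sum(cs)
  out <- array(0, out_d)
  at <- 0
  for (x in xs) {
    idx <- (at + 1):(at + dim(x)[nd])
    out <- assign_last(out, idx, x)
    at <- at + dim(x)[nd]
  }
  out
}

slice_last <- function(x, idx) {
  nd <- length(dim(x))
  switch(as.character(nd),
    "2" = x[, idx, drop = FALSE],
    "3" = x[, , idx, drop = FALSE],
    "4" = x[, , , idx, drop = FALSE],
    "5" = x[, , , , idx, drop = FALSE],
    stop("unsupported rank"))
}

assign_last <- function(x, idx, value) {
  nd <- length(dim(x))
  switch(as.character(nd),
    "2" = { x[, idx] <- value; x },
    "3" = { x[, , idx] <- value; x },
    "4" = { x[, , , idx] <- value; x },
    "5" = { x[, , , , idx] <- value; x },
    stop("unsupported rank"))
}

# partial residual: add the second input's leading channels onto the
# leading channels of the first (parameter-free identity side-path used to
# condition the joint blocks; widths need not match, the overlap is used)
.padres_fw <- function(lay, inputs) {
  y <- inputs[[1]]; x <- inputs[[2]]
  cx <- dim(x)[length(dim(x))]
  cy <- dim(y)[length(dim(y))]
  cm <- min(cx, cy)
  idx <- seq_len(cm)
  lay$cache <- list(cm = cm, cx = cx)
  assign_last(y, idx, slice_last(y, idx) + slice_last(x, idx))
}

.padres_bw <- function(lay, dy) {
  cm <- lay$cache$cm; cx <- lay$cache$cx
  dx <- slice_last(dy, seq_len(cm))
  if (cx > cm) {
    d <- dim(dx); d[length(d)] <- cx
    full <- array(0, d)
    dx <- assign_last(full, seq_len(cm), dx)
  }
  list(dy, dx)
}
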