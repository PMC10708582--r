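# Farneback dense optical flow.
#
# Each frame neighborhood is approximated by a quadratic polynomial
# f(u) ~ u' A u + b' u + c  with Gaussian applicability (polynomial
# expansion); equating the expansions of two frames under a displacement d
# gives A d = -0.5 * (b2 - b1), which is solved per pixel after window
# averaging of the normal equations, iterated and refined over an image
# pyramid. This mirrors the standard solver settings: pyramid scale 0.5,
# 3 levels, window 15, 3 iterations, poly_n 5, poly_sigma 1.2.

#' Farneback solver settings
#'
#' @param pyr_scale Pyramid downscale factor per level (0.5).
#' @param levels Number of pyramid levels (3).
#' @param winsize Averaging window size in pixels (15).
#' @param iterations Displacement refinement iterations per level (3).
#' @param poly_n Pixel neighborhood for the polynomial expansion (5).
#' @param poly_sigma Gaussian applicability width (1.2).
#' @return List of settings for [farneback_flow()].
#' @export
farneback_params <- function(pyr_scale = 0.5, levels = 3L, winsize = 15L,
                             iterations = 3L, poly_n = 5L, poly_sigma = 1.2) {
  list(pyr_scale = pyr_scale, levels = levels, winsize = winsize,
       iterations = iterations, poly_n = poly_n, poly_sigma = poly_sigma)
}

.pad_replicate <- function(m, py, px) {
  ri <- c(rep(1L, py), seq_len(nrow(m)), rep(nrow(m), py))
  ci <- c(rep(1L, px), seq_len(ncol(m)), rep(ncol(m), px))
  m[ri, ci, drop = FALSE]
}

# correlation result(x) = sum_u k(u) f(x + u), separable, replicate border
.corr_sep <- function(m, k_row, k_col) {
  hr <- (length(k_row) - 1L) %/% 2L
  hc <- (length(k_col) - 1L) %/% 2L
  mp <- .pad_replicate(m, hr, hc)
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, ncol(mp))
  for (u in seq_along(k_row))
    tmp <- tmp + k_row[u] * mp[(u - 1L) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (u in seq_along(k_col))
    out <- out + k_col[u] * tmp[, (u - 1L) + seq_len(nc), drop = FALSE]
  out
}

# Quadratic polynomial expansion; returns per-pixel A (2x2 symmetric) and b.
.poly_exp <- function(f, n = 5L, sigma = 1.2) {
  hw <- n %/% 2L
  x <- -hw:hw
  a <- exp(-x^2 / (2 * sigma^2))
  k0 <- a; k1 <- a * x; k2 <- a * x^2
  A <- sum(a); B <- sum(a * x^2); C <- sum(a * x^4)
  # basis order (1, x, y, x^2, y^2, xy); x = columns, y = rows
  G <- matrix(0, 6, 6)
  G[1, 1] <- A * A
  G[2, 2] <- A * B; G[3, 3] <- A * B
  G[1, 4] <- G[4, 1] <- A * B
  G[1, 5] <- G[5, 1] <- A * B
  G[4, 4] <- A * C; G[5, 5] <- A * C
  G[4, 5] <- G[5, 4] <- B * B
  G[6, 6] <- B * B
  Ginv <- solve(G)
  v <- list(
    .corr_sep(f, k0, k0),   # m00
    .corr_sep(f, k0, k1),   # m10  (x moment: k1 along columns)
    .corr_sep(f, k1, k0),   # m01  (y moment)
    .corr_sep(f, k0, k2),   # m20
    .corr_sep(f, k2, k0),   # m02
    .corr_sep(f, k1, k1)    # m11
  )
  r <- vector("list", 6)
  for (i in 1:6) {
    ri <- 0
    for (j in 1:6) if (Ginv[i, j] != 0) ri <- ri + Ginv[i, j] * v[[j]]
    r[[i]] <- ri
  }
  list(b1 = r[[2]], b2 = r[[3]],        # gradient components (x, y)
       a11 = r[[4]], a22 = r[[5]], a12 = r[[6]] / 2)
}

.box_kernel <- function(w) rep(1 / w, w)

# one refinement pass at a single scale
.flow_iterate <- function(p1, p2, dx, dy, winsize, iterations) {
  nr <- nrow(p1$b1); nc <- ncol(p1$b1)
  kw <- .box_kernel(winsize)
  colg <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rowg <- matrix(rep(seq_len(nr), nc), nr, nc)
  for (it in seq_len(iterations)) {
    ci <- pmin(pmax(round(colg + dx), 1L), nc)
    ri <- pmin(pmax(round(rowg + dy), 1L), nr)
    idx <- cbind(as.vector(ri), as.vector(ci))
    take <- function(m) matrix(m[idx], nr, nc)
    a11 <- (p1$a11 + take(p2$a11)) / 2
    a22 <- (p1$a22 + take(p2$a22)) / 2
    a12 <- (p1$a12 + take(p2$a12)) / 2
    db1 <- -0.5 * (take(p2$b1) - p1$b1) + a11 * dx + a12 * dy
    db2 <- -0.5 * (take(p2$b2) - p1$b2) + a12 * dx + a22 * dy
    g11 <- .corr_sep(a11 * a11 + a12 * a12, kw, kw)
    g12 <- .corr_sep(a11 * a12 + a12 * a22, kw, kw)
    g22 <- .corr_sep(a12 * a12 + a22 * a22, kw, kw)
    h1 <- .corr_sep(a11 * db1 + a12 * db2, kw, kw)
    h2 <- .corr_sep(a12 * db1 + a22 * db2, kw, kw)
    det <- g11 * g22 - g12 * g12
    det[abs(det) < 1e-9] <- 1e-9
    dx <- (g22 * h1 - g12 * h2) / det
    dy <- (g11 * h2 - g12 * h1) / det
  }
  list(dx = dx, dy = dy)
}

#' Dense optical flow between two grayscale frames
#'
#' @param f1,f2 `H x W` numeric matrices (any consistent intensity scale).
#' @param params Settings from [farneback_params()].
#' @return List with `dx` and `dy`, `H x W` matrices of per-pixel
#'   displacement in pixels (x = columns, y = rows), describing motion from
#'   `f1` to `f2`.
#' @export
farneback_flow <- function(f1, f2, params = farneback_params()) {
  stopifnot(identical(dim(f1), dim(f2)), length(dim(f1)) == 2L)
  # pyramid, coarse to fine
  pyr1 <- list(f1); pyr2 <- list(f2)
  lv <- 1L
  while (lv < params$levels &&
         min(dim(pyr1[[lv]])) * params$pyr_scale >= max(8, params$poly_n)) {
    nh <- max(2L, round(nrow(pyr1[[lv]]) * params$pyr_scale))
    nw <- max(2L, round(ncol(pyr1[[lv]]) * params$pyr_scale))
    pyr1[[lv + 1L]] <- resize_bilinear(array(pyr1[[lv]], c(dim(pyr1[[lv]]), 1L)), nh, nw)[, , 1]
    pyr2[[lv + 1L]] <- resize_bilinear(array(pyr2[[lv]], c(dim(pyr2[[lv]]), 1L)), nh, nw)[, , 1]
    lv <- lv + 1L
  }
  dx <- dy <- matrix(0, nrow(pyr1[[lv]]), ncol(pyr1[[lv]]))
  for (l in rev(seq_len(lv))) {
    if (!identical(dim(dx), dim(pyr1[[l]]))) {
      sc_r <- nrow(pyr1[[l]]) / nrow(dx)
      sc_c <- ncol(pyr1[[l]]) / ncol(dx)
      dx <- resize_bilinear(array(dx, c(dim(dx), 1L)),
                            nrow(pyr1[[l]]), ncol(pyr1[[l]]))[, , 1] * sc_c
      dy <- resize_bilinear(array(dy, c(dim(dy), 1L)),
                            nrow(pyr1[[l]]), ncol(pyr1[[l]]))[, , 1] * sc_r
    }
    win <- max(3L, min(params$winsize, min(dim(pyr1[[l]])) - 1L))
    if (win %% 2L == 0L) win <- win + 1L
    p1 <- .poly_exp(pyr1[[l]], params$poly_n, params$poly_sigma)
    p2 <- .poly_exp(pyr2[[l]], params$poly_n, params$poly_sigma)
    res <- .flow_iterate(p1, p2, dx, dy, win, params$iterations)
    dx <- res$dx; dy <- res$dy
  }
  list(dx = dx, dy = dy)
}
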