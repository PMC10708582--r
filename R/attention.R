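# Scaled dot-product attention as a standalone operation.

#' Scaled dot-product attention
#'
#' `softmax(Q K' / s) V` with `s = sqrt(d_k)` under the standard convention
#' (or `s = d_k` when `scale = "dk"`). Rows of the weight matrix sum to 1
#' for any finite scores.
#'
#' @param Q,K,V Matrices with compatible dimensions: `Q` is `n x d_k`, `K`
#'   `m x d_k`, `V` `m x d_v`.
#' @param d_k Key width used in the scaling (defaults to `ncol(K)`).
#' @param scale `"sqrt_dk"` or `"dk"`.
#' @return `n x d_v` matrix of attended values.
#' @export
attention <- function(Q, K, V, d_k = ncol(K), scale = c("sqrt_dk", "dk")) {
  scale <- match.arg(scale)
  if (d_k <= 0) stop("attention: d_k must be positive")
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("attention: Q and K widths differ")
  if (nrow(K) != nrow(V)) stop("attention: K and V row counts differ")
  s <- if (scale == "dk") d_k else sqrt(d_k)
  .softmax_rows(Q %*% t(K) / s) %*% V
}

#' Attention weight matrix (row-stochastic)
#' @rdname attention
#' @export
attention_weights <- function(Q, K, d_k = ncol(K), scale = c("sqrt_dk", "dk")) {
  scale <- match.arg(scale)
  if (d_k <= 0) stop("attention: d_k must be positive")
  s <- if (scale == "dk") d_k else sqrt(d_k)
  .softmax_rows(as.matrix(Q) %*% t(as.matrix(K)) / s)
}
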