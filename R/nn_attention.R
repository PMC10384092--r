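## Attention primitives. `sdp_fw`/`sdp_bw` operate on matrices whose rows are
## queries/keys; every attention variant in the package reduces to them.

sdp_fw <- function(Q, K, V, scale) {
  S <- tcrossprod(Q, K) * scale
  P <- softmax_rows(S)
  list(out = P %*% V, P = P)
}

sdp_bw <- function(dout, P, Q, K, V, scale) {
  dV <- crossprod(P, dout)
  dP <- tcrossprod(dout, V)
  dS <- P * (dP - rowSums(dP * P))
  list(dQ = dS %*% K * scale, dK = crossprod(dS, Q) * scale, dV = dV)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`, the attention core of the model.
#' Rows of `Q` are queries, rows of `K`/`V` are keys/values, and the softmax
#' normalises over the key axis. `d_k` defaults to the key width.
#'
#' @param Q,K,V numeric matrices; `ncol(Q) == ncol(K)`, `nrow(K) == nrow(V)`.
#' @param d_k scale denominator (defaults to `ncol(K)`).
#' @return A list with `out` (`nrow(Q) x ncol(V)`) and the attention-weight
#'   matrix `P` whose rows sum to one.
#' @export
#' @examples
#' Q <- matrix(rnorm(8), 2, 4); K <- matrix(rnorm(12), 3, 4)
#' V <- matrix(rnorm(6), 3, 2)
#' a <- scaled_dot_product_attention(Q, K, V)
#' rowSums(a$P)  # all 1
scaled_dot_product_attention <- function(Q, K, V, d_k = ncol(K)) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share their inner dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows")
  if (d_k <= 0) stop("d_k must be positive")
  sdp_fw(Q, K, V, 1 / sqrt(d_k))
}

#' Sinusoidal positional encoding
#'
#' `PE(pos, 2i) = sin(pos / 10000^(2i/d_model))` and
#' `PE(pos, 2i+1) = cos(pos / 10000^(2i/d_model))`, for positions
#' `0 .. n_positions-1`. Added elementwise to the encoder input so that the
#' temporal order of the force samples survives parallel processing.
#'
#' @param n_positions number of sequence positions.
#' @param d_model width of each position (the force-space width, 6, for the
#'   encoder input).
#' @return An `n_positions x d_model` matrix.
#' @export
positional_encoding <- function(n_positions, d_model) {
  if (d_model < 2) stop("d_model must be at least 2")
  pos <- 0:(n_positions - 1L)
  pe <- matrix(0, n_positions, d_model)
  for (j in 0:(d_model - 1L)) {
    i <- j %/% 2L
    ang <- pos / 10000^(2 * i / d_model)
    pe[, j + 1L] <- if (j %% 2L == 0L) sin(ang) else cos(ang)
  }
  pe
}

## Multi-head attention over the temporal axis of a (D, T, B) stream.
## Q comes from `xq`, K and V from `xkv` (self-attention when they coincide).
nn_mha <- function(d_model, heads) {
  if (d_model %% heads != 0L) {
    stop("model width ", d_model, " is not divisible by ", heads, " heads")
  }
  dh <- d_model %/% heads
  self <- new_layer("mha")
  self$heads <- heads
  self$children <- list(wq = nn_linear(d_model, d_model, "xavier"),
                        wk = nn_linear(d_model, d_model, "xavier"),
                        wv = nn_linear(d_model, d_model, "xavier"),
                        wo = nn_linear(d_model, d_model, "xavier"))
  ## (D, T, B) -> cube of per-(head, batch) (T, dh) slices and back
  to_cube <- function(x, T_, B) {
    dim(x) <- c(dh, heads, T_, B)
    x <- aperm(x, c(3L, 1L, 2L, 4L))
    dim(x) <- c(T_, dh, heads * B)
    x
  }
  from_cube <- function(x, T_, B) {
    dim(x) <- c(T_, dh, heads, B)
    x <- aperm(x, c(2L, 3L, 1L, 4L))
    dim(x) <- c(dh * heads, T_, B)
    x
  }
  self$fw <- function(xq, xkv = xq, train = FALSE) {
    d <- dim(xq); D <- d[1]; Tq <- d[2]; B <- d[3]
    Tk <- dim(xkv)[2]
    ch <- self$children
    Q <- to_cube(ch$wq$fw(matrix(xq, D)), Tq, B)
    K <- to_cube(ch$wk$fw(matrix(xkv, D)), Tk, B)
    V <- to_cube(ch$wv$fw(matrix(xkv, D)), Tk, B)
    r <- attn_cube_fw(Q, K, V, Tq, dh, Tk, dh, heads * B, 1 / sqrt(dh))
    dim(r$P) <- c(Tq, Tk, heads * B)
    self$cache <- list(Q = Q, K = K, V = V, P = r$P, d = d, Tk = Tk)
    O <- from_cube(r$out, Tq, B)
    array(ch$wo$fw(matrix(O, D)), c(D, Tq, B))
  }
  self$bw <- function(dy) {
    cc <- self$cache
    D <- cc$d[1]; Tq <- cc$d[2]; B <- cc$d[3]; Tk <- cc$Tk
    ch <- self$children
    dO <- to_cube(ch$wo$bw(matrix(dy, D)), Tq, B)
    r <- attn_cube_bw(dO, cc$P, cc$Q, cc$K, cc$V,
                      Tq, dh, Tk, dh, heads * B, 1 / sqrt(dh))
    dQ <- from_cube(r$dQ, Tq, B)
    dK <- from_cube(r$dK, Tk, B)
    dV <- from_cube(r$dV, Tk, B)
    dxq <- array(ch$wq$bw(matrix(dQ, D)), c(D, Tq, B))
    dxkv <- array(ch$wk$bw(matrix(dK, D)) + ch$wv$bw(matrix(dV, D)),
                  c(D, Tk, B))
    list(dq = dxq, dkv = dxkv)
  }
  self
}

## Multi-channel attention block: Q, K, V are produced by (3,3)/stride-1/
## padding-1 2-D convolutions mapping in_ch -> out_ch on (C, H, W, B)
## tensors; each output channel acts as one attention head, with
## softmax(Qc Kc' / sqrt(W)) Vc computed per channel over the (H, W) map.
nn_mca <- function(c_in, c_out) {
  self <- new_layer("mca")
  self$c_out <- c_out
  self$children <- list(convq = nn_conv2d(c_in, c_out),
                        convk = nn_conv2d(c_in, c_out),
                        convv = nn_conv2d(c_in, c_out))
  ## (C, H, W, B) -> cube of per-(channel, batch) (H, W) slices and back
  to_cube <- function(x, d) {
    x <- aperm(x, c(2L, 3L, 1L, 4L))
    dim(x) <- c(d[2], d[3], d[1] * d[4])
    x
  }
  from_cube <- function(x, d) {
    dim(x) <- c(d[2], d[3], d[1], d[4])
    aperm(x, c(3L, 1L, 2L, 4L))
  }
  self$fw <- function(xq, xkv = xq, train = FALSE) {
    ch <- self$children
    d <- NULL
    Q <- ch$convq$fw(xq, train); d <- dim(Q)
    Q <- to_cube(Q, d)
    K <- to_cube(ch$convk$fw(xkv, train), d)
    V <- to_cube(ch$convv$fw(xkv, train), d)
    r <- attn_cube_fw(Q, K, V, d[2], d[3], d[2], d[3], d[1] * d[4],
                      1 / sqrt(d[3]))
    dim(r$P) <- c(d[2], d[2], d[1] * d[4])
    self$cache <- list(Q = Q, K = K, V = V, P = r$P, d = d)
    from_cube(r$out, d)
  }
  self$bw <- function(dy) {
    cc <- self$cache
    d <- cc$d
    r <- attn_cube_bw(to_cube(dy, d), cc$P, cc$Q, cc$K, cc$V,
                      d[2], d[3], d[2], d[3], d[1] * d[4], 1 / sqrt(d[3]))
    ch <- self$children
    list(dq = ch$convq$bw(from_cube(r$dQ, d)),
         dkv = ch$convk$bw(from_cube(r$dK, d)) +
           ch$convv$bw(from_cube(r$dV, d)))
  }
  self
}
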