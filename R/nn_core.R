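## Minimal reverse-mode neural-network engine.
##
## Every layer is an environment holding named parameter arrays (`par`),
## matching gradient accumulators (`grad`), optional child layers
## (`children`), a `fw(x, train)` closure that caches what backward needs,
## and a `bw(dy)` closure that accumulates parameter gradients and returns
## the gradient w.r.t. its input.  All heavy lifting is expressed as matrix
## products so BLAS does the arithmetic; batches are folded into the column
## dimension wherever possible.
##
## Tensor layout conventions (column-major throughout):
##   stream tensors  (D, T, B)   feature x time x batch
##   1-D conv maps   (C, L, B)   channels x length x batch
##   2-D conv maps   (C, H, W, B)
## Matrices passed to nn_linear are (d_in, N).

new_layer <- function(kind) {
  self <- new.env(parent = emptyenv())
  self$kind <- kind
  self$par <- list()
  self$grad <- list()
  self$children <- list()
  self
}

add_par <- function(self, name, value) {
  self$par[[name]] <- value
  z <- value
  z[] <- 0
  self$grad[[name]] <- z
  invisible(self)
}

## Depth-first list of every stateful layer under `layer` (inclusive):
## layers with trainable parameters or non-trained buffers (running
## batch-norm statistics).
collect_layers <- function(layer) {
  out <- list()
  if (length(layer$par) > 0L || length(layer$buf) > 0L) out <- list(layer)
  for (ch in layer$children) out <- c(out, collect_layers(ch))
  out
}

#' Number of trainable parameters in a model
#' @param model a model built by [build_tfsformer()] or [build_baseline()].
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(collect_layers(model),
             function(l) sum(vapply(l$par, length, 1L)), 1))
}

## Deep-copy all parameters and buffers (for checkpointing / best-epoch
## restore). Buffers carry the batch-norm running statistics, which belong
## to a trained state just as much as the weights do.
get_params <- function(model) {
  lapply(collect_layers(model), function(l) list(par = l$par, buf = l$buf))
}

set_params <- function(model, params) {
  layers <- collect_layers(model)
  stopifnot(length(layers) == length(params))
  for (i in seq_along(layers)) {
    layers[[i]]$par <- params[[i]]$par
    layers[[i]]$buf <- params[[i]]$buf
  }
  invisible(model)
}

zero_grads <- function(model) {
  for (l in collect_layers(model)) {
    for (nm in names(l$grad)) l$grad[[nm]][] <- 0
  }
  invisible(model)
}

## ---------------------------------------------------------------- layers --

nn_linear <- function(d_in, d_out, init = c("he", "xavier")) {
  init <- match.arg(init)
  self <- new_layer("linear")
  sdv <- if (init == "he") sqrt(2 / d_in) else sqrt(1 / d_in)
  add_par(self, "W", matrix(stats::rnorm(d_out * d_in, sd = sdv), d_out, d_in))
  add_par(self, "b", numeric(d_out))
  self$fw <- function(x, train = FALSE) {
    self$cache <- x
    self$par$W %*% x + self$par$b
  }
  self$bw <- function(dy) {
    self$grad$W <- self$grad$W + tcrossprod(dy, self$cache)
    self$grad$b <- self$grad$b + rowSums(dy)
    crossprod(self$par$W, dy)
  }
  self
}

nn_relu <- function() {
  self <- new_layer("relu")
  self$fw <- function(x, train = FALSE) {
    m <- x > 0
    self$cache <- m
    x * m
  }
  self$bw <- function(dy) dy * self$cache
  self
}

## 1-D convolution, stride 1. Weight rows index output channels; columns run
## over (input channel fastest, kernel offset slowest), matching the im2col
## buffer built below.
nn_conv1d <- function(c_in, c_out, kernel = 3L, pad = 1L) {
  self <- new_layer("conv1d")
  self$c_in <- c_in; self$c_out <- c_out
  add_par(self, "W", matrix(stats::rnorm(c_out * c_in * kernel,
                                         sd = sqrt(2 / (c_in * kernel))),
                            c_out, c_in * kernel))
  add_par(self, "b", numeric(c_out))
  self$fw <- function(x, train = FALSE) {
    d <- dim(x)
    check_dim(x, c(c_in, NA, NA), "conv1d input")
    L <- d[2]; B <- d[3]
    xp <- if (pad > 0L) {
      tmp <- array(0, c(c_in, L + 2L * pad, B))
      tmp[, (pad + 1L):(pad + L), ] <- x
      tmp
    } else x
    Xcol <- array(0, c(c_in, kernel, L, B))
    for (t in seq_len(kernel)) Xcol[, t, , ] <- xp[, t:(t + L - 1L), ]
    dim(Xcol) <- c(c_in * kernel, L * B)
    y <- self$par$W %*% Xcol + self$par$b
    self$cache <- list(Xcol = Xcol, L = L, B = B)
    array(y, c(c_out, L, B))
  }
  self$bw <- function(dy) {
    cc <- self$cache; L <- cc$L; B <- cc$B
    dim(dy) <- c(c_out, L * B)
    self$grad$W <- self$grad$W + tcrossprod(dy, cc$Xcol)
    self$grad$b <- self$grad$b + rowSums(dy)
    dX <- crossprod(self$par$W, dy)
    dim(dX) <- c(c_in, kernel, L, B)
    dxp <- array(0, c(c_in, L + 2L * pad, B))
    for (t in seq_len(kernel)) {
      dxp[, t:(t + L - 1L), ] <- dxp[, t:(t + L - 1L), ] + dX[, t, , ]
    }
    dx <- if (pad > 0L) dxp[, (pad + 1L):(pad + L), , drop = FALSE] else dxp
    dim(dx) <- c(c_in, L, B)
    dx
  }
  self
}

## 2-D convolution, (3,3) kernel, stride (1,1), padding 1 by default.
nn_conv2d <- function(c_in, c_out, kernel = 3L, pad = 1L) {
  self <- new_layer("conv2d")
  self$c_in <- c_in; self$c_out <- c_out
  add_par(self, "W", matrix(stats::rnorm(c_out * c_in * kernel * kernel,
                                         sd = sqrt(2 / (c_in * kernel * kernel))),
                            c_out, c_in * kernel * kernel))
  add_par(self, "b", numeric(c_out))
  self$fw <- function(x, train = FALSE) {
    d <- dim(x)
    check_dim(x, c(c_in, NA, NA, NA), "conv2d input")
    self$cache <- x
    conv2d_fw_cpp(x, self$par$W, self$par$b,
                  d[1], d[2], d[3], d[4], kernel, pad)
  }
  self$bw <- function(dy) {
    d <- dim(self$cache)
    r <- conv2d_bw_cpp(self$cache, dy, self$par$W,
                       d[1], d[2], d[3], d[4], kernel, pad)
    self$grad$W <- self$grad$W + r$dW
    self$grad$b <- self$grad$b + r$db
    r$dx
  }
  self
}

## Batch normalisation over the leading (channel) axis of a channel-first
## tensor; batch statistics in training mode, running statistics in eval.
nn_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  self <- new_layer("batchnorm")
  add_par(self, "gamma", rep(1, C))
  add_par(self, "beta", numeric(C))
  self$buf <- list(rmean = numeric(C), rvar = rep(1, C))
  self$fw <- function(x, train = FALSE) {
    d <- dim(x)
    xm <- matrix(x, C)
    if (train) {
      mu <- rowMeans(xm)
      v <- rowMeans(xm * xm) - mu * mu
      v[v < 0] <- 0
      self$buf$rmean <- (1 - momentum) * self$buf$rmean + momentum * mu
      self$buf$rvar <- (1 - momentum) * self$buf$rvar + momentum * v
    } else {
      mu <- self$buf$rmean; v <- self$buf$rvar
    }
    istd <- 1 / sqrt(v + eps)
    xhat <- (xm - mu) * istd
    y <- self$par$gamma * xhat + self$par$beta
    self$cache <- list(xhat = xhat, istd = istd, train = train, d = d)
    dim(y) <- d
    y
  }
  self$bw <- function(dy) {
    cc <- self$cache
    dym <- matrix(dy, C)
    self$grad$gamma <- self$grad$gamma + rowSums(dym * cc$xhat)
    self$grad$beta <- self$grad$beta + rowSums(dym)
    if (cc$train) {
      N <- ncol(dym)
      s1 <- rowSums(dym)
      s2 <- rowSums(dym * cc$xhat)
      dx <- (self$par$gamma * cc$istd / N) * (N * dym - s1 - cc$xhat * s2)
    } else {
      dx <- self$par$gamma * cc$istd * dym
    }
    dim(dx) <- cc$d
    dx
  }
  self
}

## Layer normalisation along the leading (feature) axis of a (D, ...) tensor.
nn_layernorm <- function(D, eps = 1e-5) {
  self <- new_layer("layernorm")
  add_par(self, "gamma", rep(1, D))
  add_par(self, "beta", numeric(D))
  self$fw <- function(x, train = FALSE) {
    d <- dim(x) %||% c(D, length(x) / D)
    xm <- matrix(x, D)
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = D)
    istd <- 1 / sqrt(colMeans(xc * xc) + eps)
    xhat <- xc * rep(istd, each = D)
    y <- self$par$gamma * xhat + self$par$beta
    self$cache <- list(xhat = xhat, istd = istd, d = d)
    dim(y) <- d
    y
  }
  self$bw <- function(dy) {
    cc <- self$cache
    dym <- matrix(dy, D)
    self$grad$gamma <- self$grad$gamma + rowSums(dym * cc$xhat)
    self$grad$beta <- self$grad$beta + rowSums(dym)
    dxh <- dym * self$par$gamma
    s1 <- colSums(dxh)
    s2 <- colSums(dxh * cc$xhat)
    dx <- rep(cc$istd / D, each = D) *
      (D * dxh - rep(s1, each = D) - cc$xhat * rep(s2, each = D))
    dim(dx) <- cc$d
    dx
  }
  self
}

## Max pooling, kernel (2,2), stride 2, on (C, H, W, B); H and W must be even.
nn_maxpool2 <- function() {
  self <- new_layer("maxpool2")
  self$fw <- function(x, train = FALSE) {
    d <- dim(x)
    stopifnot(d[2] %% 2L == 0L, d[3] %% 2L == 0L)
    io <- seq(1L, d[2], 2L); jo <- seq(1L, d[3], 2L)
    a11 <- x[, io, jo, , drop = FALSE]
    a21 <- x[, io + 1L, jo, , drop = FALSE]
    a12 <- x[, io, jo + 1L, , drop = FALSE]
    a22 <- x[, io + 1L, jo + 1L, , drop = FALSE]
    y <- pmax(a11, a21, a12, a22)
    m11 <- a11 == y
    m21 <- (a21 == y) & !m11
    m12 <- (a12 == y) & !(m11 | m21)
    m22 <- !(m11 | m21 | m12)
    self$cache <- list(d = d, io = io, jo = jo, m = list(m11, m21, m12, m22))
    y
  }
  self$bw <- function(dy) {
    cc <- self$cache
    dx <- array(0, cc$d)
    io <- cc$io; jo <- cc$jo; m <- cc$m
    dx[, io, jo, ] <- dy * m[[1]]
    dx[, io + 1L, jo, ] <- dy * m[[2]]
    dx[, io, jo + 1L, ] <- dy * m[[3]]
    dx[, io + 1L, jo + 1L, ] <- dy * m[[4]]
    dx
  }
  self
}

## Fully connected chain with ReLU between consecutive layers (never after
## the last), acting on (dims[1], N) matrices.
nn_mlp <- function(dims, init = "he") {
  self <- new_layer("mlp")
  nlin <- length(dims) - 1L
  for (i in seq_len(nlin)) {
    self$children[[paste0("lin", i)]] <- nn_linear(dims[i], dims[i + 1L], init)
    if (i < nlin) self$children[[paste0("relu", i)]] <- nn_relu()
  }
  self$fw <- function(x, train = FALSE) {
    h <- x
    for (i in seq_len(nlin)) {
      h <- self$children[[paste0("lin", i)]]$fw(h, train)
      if (i < nlin) h <- self$children[[paste0("relu", i)]]$fw(h, train)
    }
    h
  }
  self$bw <- function(dy) {
    for (i in rev(seq_len(nlin))) {
      if (i < nlin) dy <- self$children[[paste0("relu", i)]]$bw(dy)
      dy <- self$children[[paste0("lin", i)]]$bw(dy)
    }
    dy
  }
  self
}

## ------------------------------------------------------------- optimiser --

## Decoupled-weight-decay Adam. Decay is skipped for biases and
## normalisation parameters, the usual convention.
adamw_new <- function(model, lr = 1e-4, weight_decay = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$layers <- collect_layers(model)
  opt$lr <- lr; opt$wd <- weight_decay
  opt$b1 <- beta1; opt$b2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  for (l in opt$layers) {
    l$opt_m <- lapply(l$grad, function(g) { g[] <- 0; g })
    l$opt_v <- lapply(l$grad, function(g) { g[] <- 0; g })
  }
  opt
}

no_decay_par <- c("b", "beta", "gamma")

adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (l in opt$layers) {
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$opt_m[[nm]] <- opt$b1 * l$opt_m[[nm]] + (1 - opt$b1) * g
      l$opt_v[[nm]] <- opt$b2 * l$opt_v[[nm]] + (1 - opt$b2) * g * g
      upd <- opt$lr * (l$opt_m[[nm]] / bc1) / (sqrt(l$opt_v[[nm]] / bc2) + opt$eps)
      if (!(nm %in% no_decay_par)) {
        upd <- upd + opt$lr * opt$wd * l$par[[nm]]
      }
      l$par[[nm]] <- l$par[[nm]] - upd
    }
  }
  invisible(opt)
}

## Mean absolute error and its subgradient, over every element.
mae_loss <- function(pred, target) {
  d <- pred - target
  list(value = mean(abs(d)), grad = sign(d) / length(d))
}
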