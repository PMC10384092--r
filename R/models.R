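## The TFSformer network and its comparison baselines.
##
## Encoder (dual-dimension 1-D convolution): the positional-encoded force
## window (n x 6) is first convolved along the force-space axis with the
## temporal axis acting as channels (widths 32 -> 64 -> 128 -> 256), then
## transposed and convolved along the temporal axis with force-space as
## channels (6 -> 36 -> 108 -> 256). The width progressions force this axis
## assignment: a kernel-3/stride-1/padding-1 convolution preserves spatial
## length, so a growing width can only be a channel count. Each convolution
## carries a kernel-1 residual projection, ReLU, then batch normalisation.
##
## Decoder (deep multi-channel attention): the VMD block (n x 3K) is
## expanded by two linear maps to the (256 x 256) stream, passed through
## multi-head self-attention over the temporal axis, then through four
## multi-channel attention blocks with channel schedule 8 -> 16 -> 32 -> 64
## and (2,2)/stride-2 max pooling between consecutive blocks
## (spatial 256 -> 128 -> 64 -> 32). The first block cross-attends: its
## queries come from the decoder stream and its keys/values from the
## encoder output; later blocks self-attend. A feed-forward stack over the
## last axis and a final flatten-and-project head produce the k x 4 angle
## block.

#' Model architecture configuration
#'
#' Collects every architecture hyperparameter. `width_multiplier` scales
#' all channel/width schedules uniformly (stream width, encoder widths,
#' channel schedule, feed-forward inner dims) so the full composition can
#' be exercised at desk scale; the data dimensions `n`, `force_width` and
#' `k` are never scaled.
#'
#' @param k prediction horizon (1, 3 or 6 in the reference tasks).
#' @param n input window length (default 32).
#' @param width_multiplier uniform width scale in (0, 1]; 1 is the
#'   full-size network, 0.25 the test scale.
#' @param heads number of heads in the decoder's multi-head self-attention
#'   (must divide the stream width).
#' @param force_width number of force channels (6).
#' @param vmd_modes VMD modes per channel (3), so the decoder input width
#'   is `force_width * vmd_modes`.
#' @param mlp_hidden hidden width of the two-linear output stack of the CNN
#'   baseline; defaults to the stream width.
#' @param n_enc_layers,n_dec_layers layer counts of the vanilla transformer
#'   baseline.
#' @return A list of class `model_config` with the derived width schedules
#'   `stream` (decoder stream width), `enc_t`, `enc_f` (encoder channel
#'   schedules), `channels` (multi-channel attention schedule) and
#'   `ffn_inner`.
#' @export
model_config <- function(k = 1L, n = 32L, width_multiplier = 1,
                         heads = 8L, force_width = 6L, vmd_modes = 3L,
                         mlp_hidden = NULL,
                         n_enc_layers = 2L, n_dec_layers = 2L) {
  wm <- width_multiplier
  stopifnot(wm > 0, wm <= 1, k >= 1L, n >= 4L)
  stream <- as.integer(round(256 * wm))
  if (stream %% 8L != 0L || stream %% heads != 0L) {
    stop("width_multiplier must give a stream width divisible by 8 and by ",
         heads, " heads (got ", stream, ")")
  }
  channels <- as.integer(pmax(1, round(c(8, 16, 32, 64) * wm)))
  if (any(diff(channels) <= 0L)) {
    stop("channel schedule must be strictly increasing; width_multiplier ",
         wm, " gives (", paste(channels, collapse = ","), ")")
  }
  cfg <- list(
    k = as.integer(k), n = as.integer(n),
    width_multiplier = wm,
    heads = as.integer(heads),
    force_width = as.integer(force_width),
    vmd_modes = as.integer(vmd_modes),
    stream = stream,
    enc_t = as.integer(c(round(64 * wm), round(128 * wm), stream)),
    enc_f = as.integer(c(round(36 * wm), round(108 * wm), stream)),
    channels = channels,
    ffn_inner = as.integer(pmax(4, round(c(1024, 256) * wm))),
    mlp_hidden = as.integer(mlp_hidden %||% stream),
    n_enc_layers = as.integer(n_enc_layers),
    n_dec_layers = as.integer(n_dec_layers))
  structure(cfg, class = "model_config")
}

## ----------------------------------------------------------------- encoder

## One conv block: y = batchnorm(relu(conv3(x) + conv1(x))).
enc_block <- function(c_in, c_out, prefix) {
  l <- list()
  l[[paste0(prefix, "_conv")]] <- nn_conv1d(c_in, c_out, kernel = 3L, pad = 1L)
  l[[paste0(prefix, "_res")]] <- nn_conv1d(c_in, c_out, kernel = 1L, pad = 0L)
  l[[paste0(prefix, "_relu")]] <- nn_relu()
  l[[paste0(prefix, "_bn")]] <- nn_batchnorm(c_out)
  l
}

build_encoder <- function(cfg) {
  self <- new_layer("encoder")
  tw <- c(cfg$n, cfg$enc_t)
  fw_ <- c(cfg$force_width, cfg$enc_f)
  ch <- list()
  for (i in 1:3) ch <- c(ch, enc_block(tw[i], tw[i + 1], paste0("t", i)))
  for (i in 1:3) ch <- c(ch, enc_block(fw_[i], fw_[i + 1], paste0("f", i)))
  self$children <- ch
  run_block <- function(h, prefix, train) {
    ch <- self$children
    a <- ch[[paste0(prefix, "_conv")]]$fw(h, train)
    r <- ch[[paste0(prefix, "_res")]]$fw(h, train)
    z <- ch[[paste0(prefix, "_relu")]]$fw(a + r, train)
    ch[[paste0(prefix, "_bn")]]$fw(z, train)
  }
  back_block <- function(dy, prefix) {
    ch <- self$children
    dz <- ch[[paste0(prefix, "_bn")]]$bw(dy)
    ds <- ch[[paste0(prefix, "_relu")]]$bw(dz)
    ch[[paste0(prefix, "_conv")]]$bw(ds) + ch[[paste0(prefix, "_res")]]$bw(ds)
  }
  self$fw <- function(x, train = FALSE) {
    ## x: (n, force_width, B) read as (channels = n, length = force_width, B)
    check_dim(x, c(cfg$n, cfg$force_width, NA), "encoder input")
    shapes <- list()
    h <- x
    for (i in 1:3) {
      h <- run_block(h, paste0("t", i), train)
      shapes[[paste0("t", i)]] <- dim(h)[1:2]
    }
    h <- aperm(h, c(2L, 1L, 3L))           # (force_width, t3, B)
    for (i in 1:3) {
      h <- run_block(h, paste0("f", i), train)
      shapes[[paste0("f", i)]] <- dim(h)[1:2]
    }
    self$shapes <- shapes
    h                                       # (stream, stream, B)
  }
  self$bw <- function(dy) {
    for (i in 3:1) dy <- back_block(dy, paste0("f", i))
    dy <- aperm(dy, c(2L, 1L, 3L))
    for (i in 3:1) dy <- back_block(dy, paste0("t", i))
    dy
  }
  self
}

## ----------------------------------------------------------------- decoder

build_decoder <- function(cfg) {
  self <- new_layer("decoder")
  S <- cfg$stream
  vin <- cfg$force_width * cfg$vmd_modes
  chs <- cfg$channels
  s8 <- S %/% 8L
  ch <- list(
    expand_t = nn_linear(cfg$n, S),
    expand_f = nn_linear(vin, S),
    mha = nn_mha(S, cfg$heads),
    mca1 = nn_mca(1L, chs[1]),
    pool1 = nn_maxpool2(),
    mca2 = nn_mca(chs[1], chs[2]),
    pool2 = nn_maxpool2(),
    mca3 = nn_mca(chs[2], chs[3]),
    pool3 = nn_maxpool2(),
    mca4 = nn_mca(chs[3], chs[4]),
    ffn = nn_mlp(c(s8, cfg$ffn_inner, s8)),
    head = nn_linear(chs[4] * s8 * s8, cfg$k * 4L))
  self$children <- ch
  self$fw <- function(v, enc_out, train = FALSE) {
    check_dim(v, c(cfg$n, vin, NA), "decoder VMD input")
    B <- dim(v)[3]
    ## temporal expansion n -> S, then feature expansion vin -> S
    h <- array(ch$expand_t$fw(matrix(v, cfg$n)), c(S, vin, B))
    h <- aperm(h, c(2L, 1L, 3L))
    h <- array(ch$expand_f$fw(matrix(h, vin)), c(S, S, B))
    h <- ch$mha$fw(h, h, train)
    xq <- h; dim(xq) <- c(1L, S, S, B)
    ek <- enc_out; dim(ek) <- c(1L, S, S, B)
    shapes <- list()
    b1 <- ch$mca1$fw(xq, ek, train); shapes$mca1 <- dim(b1)[1:3]
    p1 <- ch$pool1$fw(b1)
    b2 <- ch$mca2$fw(p1, p1, train); shapes$mca2 <- dim(b2)[1:3]
    p2 <- ch$pool2$fw(b2)
    b3 <- ch$mca3$fw(p2, p2, train); shapes$mca3 <- dim(b3)[1:3]
    p3 <- ch$pool3$fw(b3)
    b4 <- ch$mca4$fw(p3, p3, train); shapes$mca4 <- dim(b4)[1:3]
    self$shapes <- shapes
    ## feed-forward along the last spatial axis
    xf <- aperm(b4, c(3L, 1L, 2L, 4L))      # (W, C, H, B)
    df <- dim(xf)
    y <- ch$ffn$fw(matrix(xf, df[1]), train)
    y <- aperm(array(y, df), c(2L, 3L, 1L, 4L))
    self$cache <- list(B = B, dflat = dim(y))
    ch$head$fw(matrix(y, prod(dim(y)[1:3])), train)   # (k*4, B)
  }
  self$bw <- function(dy) {
    cc <- self$cache
    B <- cc$B
    dflat <- cc$dflat                        # (C, H, W, B)
    dyy <- array(ch$head$bw(dy), dflat)
    dxf <- aperm(dyy, c(3L, 1L, 2L, 4L))
    dff <- ch$ffn$bw(matrix(dxf, dim(dxf)[1]))
    db4 <- aperm(array(dff, dim(dxf)), c(2L, 3L, 1L, 4L))
    r4 <- ch$mca4$bw(db4); dp3 <- r4$dq + r4$dkv
    db3 <- ch$pool3$bw(dp3)
    r3 <- ch$mca3$bw(db3); dp2 <- r3$dq + r3$dkv
    db2 <- ch$pool2$bw(dp2)
    r2 <- ch$mca2$bw(db2); dp1 <- r2$dq + r2$dkv
    db1 <- ch$pool1$bw(dp1)
    r1 <- ch$mca1$bw(db1)
    dxq <- r1$dq; dim(dxq) <- c(S, S, B)
    denc <- r1$dkv; dim(denc) <- c(S, S, B)
    rm <- ch$mha$bw(dxq)
    dh <- rm$dq + rm$dkv
    dh <- array(ch$expand_f$bw(matrix(dh, S)),
                c(cfg$force_width * cfg$vmd_modes, S, B))
    dh <- aperm(dh, c(2L, 1L, 3L))
    dv <- array(ch$expand_t$bw(matrix(dh, S)),
                c(cfg$n, cfg$force_width * cfg$vmd_modes, B))
    list(dv = dv, denc = denc)
  }
  self
}

## ------------------------------------------------------------- TFSformer --

#' Build a TFSformer model
#'
#' Composes positional encoding, the dual-dimension convolutional encoder
#' and the VMD-fed deep multi-channel attention decoder. Inputs are
#' standardised per force channel with the training-set statistics attached
#' to the model; targets stay in radians.
#'
#' @param config a [model_config()].
#' @param stats optional list with per-channel `mu` and `sd` (length-6
#'   each); identity when omitted.
#' @param vmd a [vmd_config()] used when the forward pass has to decompose
#'   raw windows itself.
#' @param seed optional integer seed for parameter initialisation.
#' @return A model object (environment) of kind `"tfsformer"`.
#' @export
build_tfsformer <- function(config, stats = NULL, vmd = vmd_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  self <- new_layer("tfsformer")
  self$config <- config
  self$vmd <- vmd
  self$stats <- stats %||% list(mu = numeric(config$force_width),
                                sd = rep(1, config$force_width))
  self$pe <- positional_encoding(config$n, config$force_width)
  self$children <- list(encoder = build_encoder(config),
                        decoder = build_decoder(config))
  self$fw <- function(x, v, train = FALSE) {
    ch <- self$children
    xn <- standardize_windows(x, self$stats)
    xpe <- xn + as.vector(self$pe)
    eo <- ch$encoder$fw(xpe, train)
    ch$decoder$fw(v, eo, train)
  }
  self$bw <- function(dy) {
    ch <- self$children
    r <- ch$decoder$bw(dy)
    ch$encoder$bw(r$denc)
    invisible(NULL)
  }
  self
}

## Standardise (n, 6, B) windows with per-channel statistics.
standardize_windows <- function(x, stats) {
  n <- dim(x)[1]
  (x - rep(stats$mu, each = n)) / rep(stats$sd, each = n)
}

#' Forward pass of a model on raw force windows
#'
#' Standardises the windows with the model's attached statistics, computes
#' the VMD block for each window when the model needs one (per-window
#' decomposition unless `vmd_blocks` is supplied, e.g. from session-scope
#' decomposition), and returns the predicted angle blocks.
#'
#' @param model a model from [build_tfsformer()] or [build_baseline()].
#' @param windows `n x 6 x B` array of raw force windows (a single `n x 6`
#'   matrix is accepted).
#' @param vmd_blocks optional precomputed `n x (6 K) x B` array of VMD
#'   modes of the standardised windows.
#' @return A `k x 4 x B` array of predicted joint-angle blocks (radians).
#' @export
model_forward <- function(model, windows, vmd_blocks = NULL) {
  cfg <- model$config
  if (length(dim(windows)) == 2L) dim(windows) <- c(dim(windows), 1L)
  check_dim(windows, c(cfg$n, cfg$force_width, NA), "force windows")
  B <- dim(windows)[3]
  if (model$needs_vmd %||% TRUE && is.null(vmd_blocks)) {
    xn <- standardize_windows(windows, model$stats)
    vmd_blocks <- array(0, c(cfg$n, cfg$force_width * cfg$vmd_modes, B))
    for (b in seq_len(B)) {
      vmd_blocks[, , b] <- decompose_window(xn[, , b], model$vmd)
    }
  }
  out <- model$fw(windows, vmd_blocks, train = FALSE)
  array(out, c(cfg$k, 4L, B))
}

## ------------------------------------------------------------- baselines --

## Vanilla post-norm transformer encoder/decoder layers used by the
## `transformer` and `cnn_transformer` baselines. No padding mask and no
## attention mask: every query sees all positions.
tr_enc_layer <- function(d, heads, inner, prefix) {
  l <- list()
  l[[paste0(prefix, "_mha")]] <- nn_mha(d, heads)
  l[[paste0(prefix, "_ln1")]] <- nn_layernorm(d)
  l[[paste0(prefix, "_ffn")]] <- nn_mlp(c(d, inner, d))
  l[[paste0(prefix, "_ln2")]] <- nn_layernorm(d)
  l
}

tr_dec_layer <- function(d, heads, inner, prefix) {
  l <- list()
  l[[paste0(prefix, "_self")]] <- nn_mha(d, heads)
  l[[paste0(prefix, "_ln1")]] <- nn_layernorm(d)
  l[[paste0(prefix, "_cross")]] <- nn_mha(d, heads)
  l[[paste0(prefix, "_ln2")]] <- nn_layernorm(d)
  l[[paste0(prefix, "_ffn")]] <- nn_mlp(c(d, inner, d))
  l[[paste0(prefix, "_ln3")]] <- nn_layernorm(d)
  l
}

run_enc_layer <- function(ch, prefix, x, train) {
  d <- dim(x)
  a <- ch[[paste0(prefix, "_mha")]]$fw(x, x, train)
  x <- ch[[paste0(prefix, "_ln1")]]$fw(x + a, train)
  f <- array(ch[[paste0(prefix, "_ffn")]]$fw(matrix(x, d[1]), train), d)
  ch[[paste0(prefix, "_ln2")]]$fw(x + f, train)
}

back_enc_layer <- function(ch, prefix, dy) {
  d <- dim(dy)
  dy <- ch[[paste0(prefix, "_ln2")]]$bw(dy)
  df <- array(ch[[paste0(prefix, "_ffn")]]$bw(matrix(dy, d[1])), d)
  dy <- dy + df
  dy <- ch[[paste0(prefix, "_ln1")]]$bw(dy)
  r <- ch[[paste0(prefix, "_mha")]]$bw(dy)
  dy + r$dq + r$dkv
}

run_dec_layer <- function(ch, prefix, q, mem, train) {
  d <- dim(q)
  a <- ch[[paste0(prefix, "_self")]]$fw(q, q, train)
  q <- ch[[paste0(prefix, "_ln1")]]$fw(q + a, train)
  c2 <- ch[[paste0(prefix, "_cross")]]$fw(q, mem, train)
  q <- ch[[paste0(prefix, "_ln2")]]$fw(q + c2, train)
  f <- array(ch[[paste0(prefix, "_ffn")]]$fw(matrix(q, d[1]), train), d)
  ch[[paste0(prefix, "_ln3")]]$fw(q + f, train)
}

## returns list(dq, dmem)
back_dec_layer <- function(ch, prefix, dy) {
  d <- dim(dy)
  dy <- ch[[paste0(prefix, "_ln3")]]$bw(dy)
  df <- array(ch[[paste0(prefix, "_ffn")]]$bw(matrix(dy, d[1])), d)
  dy <- dy + df
  dy <- ch[[paste0(prefix, "_ln2")]]$bw(dy)
  r <- ch[[paste0(prefix, "_cross")]]$bw(dy)
  dy <- dy + r$dq
  dy <- ch[[paste0(prefix, "_ln1")]]$bw(dy)
  rs <- ch[[paste0(prefix, "_self")]]$bw(dy)
  list(dq = dy + rs$dq + rs$dkv, dmem = r$dkv)
}

## Shared decoder-side plumbing of the two transformer baselines: k learned
## query positions (sinusoidal PE as fixed content), n_dec_layers decoder
## layers, and a per-position linear head to the four joint angles.
vanilla_decoder_fw <- function(self, mem, train) {
  cfg <- self$config
  d <- cfg$stream
  B <- dim(mem)[3]
  q <- array(rep(as.vector(t(self$pe_dec)), B), c(d, cfg$k, B))
  for (i in seq_len(cfg$n_dec_layers)) {
    q <- run_dec_layer(self$children, paste0("dec", i), q, mem, train)
  }
  self$dec_dim <- dim(q)
  out <- self$children$head$fw(matrix(q, d), train)   # (4, k*B)
  out <- array(out, c(4L, cfg$k, B))
  out <- aperm(out, c(2L, 1L, 3L))                    # (k, 4, B)
  matrix(out, cfg$k * 4L)
}

vanilla_decoder_bw <- function(self, dy) {
  cfg <- self$config
  d <- cfg$stream
  B <- ncol(dy)
  dout <- array(dy, c(cfg$k, 4L, B))
  dout <- aperm(dout, c(2L, 1L, 3L))
  dq <- array(self$children$head$bw(matrix(dout, 4L)), self$dec_dim)
  dmem <- 0
  for (i in rev(seq_len(cfg$n_dec_layers))) {
    r <- back_dec_layer(self$children, paste0("dec", i), dq)
    dq <- r$dq
    dmem <- dmem + r$dmem
  }
  dmem
}

#' Build a comparison baseline model
#'
#' Three reference architectures sharing the `(n x 6) -> (k x 4)` contract
#' and the training harness:
#' \describe{
#'   \item{`cnn`}{the TFSformer convolutional encoder followed by two
#'     linear output layers (no attention anywhere).}
#'   \item{`transformer`}{a vanilla encoder-decoder transformer with
#'     neither padding nor attention masks, so every position attends to
#'     all 32 input positions.}
#'   \item{`cnn_transformer`}{the TFSformer convolutional encoder feeding a
#'     vanilla transformer decoder.}
#' }
#'
#' @param kind one of `"cnn"`, `"transformer"`, `"cnn_transformer"`.
#' @param config a [model_config()].
#' @param stats optional per-channel standardisation statistics.
#' @param seed optional integer seed for initialisation.
#' @return A model object (environment) with `kind` as given.
#' @export
build_baseline <- function(kind = c("cnn", "transformer", "cnn_transformer"),
                           config, stats = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  self <- new_layer(kind)
  self$config <- cfg
  self$needs_vmd <- FALSE
  self$stats <- stats %||% list(mu = numeric(cfg$force_width),
                                sd = rep(1, cfg$force_width))
  self$pe <- positional_encoding(cfg$n, cfg$force_width)
  d <- cfg$stream

  if (kind == "cnn") {
    self$children <- list(
      encoder = build_encoder(cfg),
      out1 = nn_linear(d * d, cfg$mlp_hidden),
      out_relu = nn_relu(),
      out2 = nn_linear(cfg$mlp_hidden, cfg$k * 4L))
    self$fw <- function(x, v = NULL, train = FALSE) {
      ch <- self$children
      xn <- standardize_windows(x, self$stats) + as.vector(self$pe)
      eo <- ch$encoder$fw(xn, train)
      B <- dim(eo)[3]
      h <- ch$out1$fw(matrix(eo, d * d), train)
      h <- ch$out_relu$fw(h, train)
      ch$out2$fw(h, train)
    }
    self$bw <- function(dy) {
      ch <- self$children
      dh <- ch$out2$bw(dy)
      dh <- ch$out_relu$bw(dh)
      deo <- ch$out1$bw(dh)
      ch$encoder$bw(array(deo, c(d, d, ncol(dy))))
      invisible(NULL)
    }
  } else if (kind == "transformer") {
    inner <- cfg$ffn_inner[1]
    ch <- list(embed = nn_linear(cfg$force_width, d))
    for (i in seq_len(cfg$n_enc_layers)) {
      ch <- c(ch, tr_enc_layer(d, cfg$heads, inner, paste0("enc", i)))
    }
    for (i in seq_len(cfg$n_dec_layers)) {
      ch <- c(ch, tr_dec_layer(d, cfg$heads, inner, paste0("dec", i)))
    }
    ch$head <- nn_linear(d, 4L)
    self$children <- ch
    self$pe_enc <- positional_encoding(cfg$n, d)
    self$pe_dec <- positional_encoding(cfg$k, d)
    self$fw <- function(x, v = NULL, train = FALSE) {
      ch <- self$children
      xn <- standardize_windows(x, self$stats)
      B <- dim(xn)[3]
      xt <- aperm(xn, c(2L, 1L, 3L))             # (6, n, B)
      h <- array(ch$embed$fw(matrix(xt, cfg$force_width), train),
                 c(d, cfg$n, B))
      h <- h + as.vector(t(self$pe_enc))
      for (i in seq_len(cfg$n_enc_layers)) {
        h <- run_enc_layer(ch, paste0("enc", i), h, train)
      }
      vanilla_decoder_fw(self, h, train)
    }
    self$bw <- function(dy) {
      ch <- self$children
      dmem <- vanilla_decoder_bw(self, dy)
      for (i in rev(seq_len(cfg$n_enc_layers))) {
        dmem <- back_enc_layer(ch, paste0("enc", i), dmem)
      }
      ch$embed$bw(matrix(dmem, d))
      invisible(NULL)
    }
  } else {                                       # cnn_transformer
    inner <- cfg$ffn_inner[1]
    ch <- list(encoder = build_encoder(cfg))
    for (i in seq_len(cfg$n_dec_layers)) {
      ch <- c(ch, tr_dec_layer(d, cfg$heads, inner, paste0("dec", i)))
    }
    ch$head <- nn_linear(d, 4L)
    self$children <- ch
    self$pe_dec <- positional_encoding(cfg$k, d)
    self$fw <- function(x, v = NULL, train = FALSE) {
      ch <- self$children
      xn <- standardize_windows(x, self$stats) + as.vector(self$pe)
      mem <- ch$encoder$fw(xn, train)            # (d, d, B)
      vanilla_decoder_fw(self, mem, train)
    }
    self$bw <- function(dy) {
      dmem <- vanilla_decoder_bw(self, dy)
      self$children$encoder$bw(dmem)
      invisible(NULL)
    }
  }
  self
}

#' List attention layers of a model
#'
#' Structural helper: returns the kinds of all parameterised descendants,
#' used e.g. to assert that the CNN baseline carries no attention
#' parameters.
#'
#' @param model a model object.
#' @return Character vector of layer kinds.
#' @export
layer_kinds <- function(model) {
  kinds <- character()
  walk <- function(l) {
    kinds <<- c(kinds, l$kind)
    for (ch in l$children) walk(ch)
  }
  walk(model)
  kinds
}
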