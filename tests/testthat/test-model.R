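test_that("scaled model asserts its dimension algebra end to end", {
  cfg <- model_config(k = 3, width_multiplier = 0.25)
  m <- build_tfsformer(cfg, seed = 1)
  B <- 2
  x <- array(rnorm(32 * 6 * B), c(32, 6, B))
  v <- array(rnorm(32 * 18 * B), c(32, 18, B))
  y <- m$fw(x, v)
  expect_equal(dim(y), c(12L, 2L))
  enc <- m$children$encoder$shapes
  expect_equal(enc$t1, c(16L, 6L)); expect_equal(enc$t3, c(64L, 6L))
  expect_equal(enc$f1, c(9L, 64L)); expect_equal(enc$f3, c(64L, 64L))
  dec <- m$children$decoder$shapes
  expect_equal(dec$mca1, c(2L, 64L, 64L))
  expect_equal(dec$mca4, c(16L, 8L, 8L))
})

test_that("the forward pass is deterministic in eval mode and batchable", {
  cfg <- model_config(k = 1, width_multiplier = 0.25)
  m <- build_tfsformer(cfg, seed = 2)
  x1 <- array(rnorm(32 * 6), c(32, 6, 1))
  v1 <- array(rnorm(32 * 18), c(32, 18, 1))
  # same window repeated in one batch -> identical predictions
  xb <- array(x1, c(32, 6, 4)); vb <- array(v1, c(32, 18, 4))
  yb <- m$fw(xb, vb)
  expect_lt(max(abs(yb - yb[, 1])), 1e-12)
  expect_equal(m$fw(x1, v1), m$fw(x1, v1))
})

test_that("construction is reproducible: same config and seed give the
           same parameter count and identical parameters", {
  cfg <- model_config(k = 1, width_multiplier = 0.25)
  m1 <- build_tfsformer(cfg, seed = 33)
  m2 <- build_tfsformer(cfg, seed = 33)
  expect_equal(count_params(m1), count_params(m2))
  expect_identical(gaitTFS:::get_params(m1), gaitTFS:::get_params(m2))
})

test_that("one backward pass reaches every parameter", {
  # k = 3 so the baselines' decoder self-attention is a real softmax; a
  # single-query attention (k = 1) has constant weights and its Q/K
  # projections legitimately receive zero gradient
  cfg <- model_config(k = 3, width_multiplier = 0.25)
  for (kind in c("tfsformer", "cnn", "transformer", "cnn_transformer")) {
    m <- if (kind == "tfsformer") build_tfsformer(cfg, seed = 4) else
      build_baseline(kind, cfg, seed = 4)
    B <- 2
    x <- array(rnorm(32 * 6 * B), c(32, 6, B))
    v <- array(rnorm(32 * 18 * B), c(32, 18, B))
    pred <- m$fw(x, v, train = TRUE)
    l <- mae_loss(pred, matrix(rnorm(length(pred)), nrow(pred)))
    zero_grads(m)
    m$bw(l$grad)
    for (lay in gaitTFS:::collect_layers(m)) {
      for (nm in names(lay$grad)) {
        expect_gt(max(abs(lay$grad[[nm]])), 0,
                  label = paste(kind, lay$kind, nm, "gradient"))
      }
    }
  }
  # the single-step TFSformer decoder also has no dead branch
  m1 <- build_tfsformer(model_config(k = 1, width_multiplier = 0.25),
                        seed = 4)
  x <- array(rnorm(32 * 6 * 2), c(32, 6, 2))
  v <- array(rnorm(32 * 18 * 2), c(32, 18, 2))
  pred <- m1$fw(x, v, train = TRUE)
  zero_grads(m1)
  m1$bw(mae_loss(pred, matrix(rnorm(length(pred)), nrow(pred)))$grad)
  for (lay in gaitTFS:::collect_layers(m1)) {
    for (nm in names(lay$grad)) {
      expect_gt(max(abs(lay$grad[[nm]])), 0,
                label = paste("tfsformer k1", lay$kind, nm, "gradient"))
    }
  }
})

test_that("all baselines honour the (B, k, 4) output contract", {
  for (k in c(1L, 3L, 6L)) {
    cfg <- model_config(k = k, width_multiplier = 0.25)
    B <- 3
    x <- array(rnorm(32 * 6 * B), c(32, 6, B))
    for (kind in c("cnn", "transformer", "cnn_transformer")) {
      m <- build_baseline(kind, cfg, seed = 5)
      out <- model_forward(m, x)
      expect_equal(dim(out), c(k, 4L, B))
    }
  }
  expect_error(build_baseline("mlp", model_config(k = 1)), "arg")
})

test_that("the CNN baseline carries no attention machinery", {
  cfg <- model_config(k = 1, width_multiplier = 0.25)
  m <- build_baseline("cnn", cfg, seed = 6)
  expect_false(any(layer_kinds(m) %in% c("mha", "mca")))
})

test_that("the transformer baseline attends densely over all 32 input
           positions (no masks)", {
  cfg <- model_config(k = 1, width_multiplier = 0.25)
  m <- build_baseline("transformer", cfg, seed = 7)
  x <- array(rnorm(32 * 6 * 2), c(32, 6, 2))
  m$fw(x)
  P <- m$children$enc1_mha$cache$P
  expect_equal(dim(P)[1:2], c(32L, 32L))
  expect_true(all(P > 0))
  expect_lt(max(abs(apply(P, 3, rowSums) - 1)), 1e-5)
})

test_that("model_forward decomposes raw windows itself when no VMD blocks
           are supplied", {
  cfg <- model_config(k = 1, width_multiplier = 0.25)
  m <- build_tfsformer(cfg, seed = 8)
  set.seed(8)
  x <- array(rnorm(32 * 6 * 2), c(32, 6, 2))
  out <- model_forward(m, x)
  expect_equal(dim(out), c(1L, 4L, 2L))
  xn <- gaitTFS:::standardize_windows(x, m$stats)
  v <- array(0, c(32, 18, 2))
  for (b in 1:2) v[, , b] <- decompose_window(xn[, , b], m$vmd)
  expect_equal(out, model_forward(m, x, v))
})

test_that("config validation rejects inconsistent widths", {
  expect_error(model_config(width_multiplier = 0.05), "stream|channel")
  expect_error(model_config(heads = 7L), "divisible|heads")
})
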