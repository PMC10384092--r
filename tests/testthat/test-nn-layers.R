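test_that("positional encoding matches its defining formula", {
  pe <- positional_encoding(32, 6)
  expect_equal(pe, naive_pe(32, 6), tolerance = 1e-12)
  # position 0: sines are 0, cosines are 1
  expect_equal(unname(pe[1, ]), c(0, 1, 0, 1, 0, 1))
  # PE(1, 0) = sin(1)
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)
  # Pythagorean identity per (sin, cos) pair
  pairs <- pe[, c(1, 3, 5)]^2 + pe[, c(2, 4, 6)]^2
  expect_lt(max(abs(pairs - 1)), 1e-12)
})

test_that("scaled dot-product attention matches the naive-loop oracle and
           its limiting cases", {
  set.seed(5)
  Q <- matrix(rnorm(16), 4); K <- matrix(rnorm(16), 4)
  V <- matrix(rnorm(16), 4)
  a <- scaled_dot_product_attention(Q, K, V)
  o <- naive_attention(Q, K, V)
  expect_lt(max(abs(a$out - o$out)), 1e-6)
  expect_lt(max(abs(rowSums(a$P) - 1)), 1e-5)

  # near-argmax selection: one huge one-hot query against identity keys
  K2 <- diag(4); V2 <- matrix(rnorm(8), 4)
  Qbig <- matrix(c(0, 0, 1e3, 0), 1)
  sel <- scaled_dot_product_attention(Qbig, K2, V2, d_k = 1)
  expect_equal(as.vector(sel$out), V2[3, ], tolerance = 1e-8)

  # zero queries: uniform attention = column means of V
  z <- scaled_dot_product_attention(matrix(0, 2, 4), K, V)
  expect_equal(z$out[1, ], colMeans(V), tolerance = 1e-12)

  expect_error(scaled_dot_product_attention(Q, K[, 1:3], V), "inner")
})

test_that("multi-head attention with one identity head reduces to scaled
           dot-product attention", {
  set.seed(9)
  d <- 4; T_ <- 5
  mha <- gaitTFS:::nn_mha(d, 1L)
  for (nm in c("wq", "wk", "wv", "wo")) {
    mha$children[[nm]]$par$W <- diag(d)
    mha$children[[nm]]$par$b <- numeric(d)
  }
  x <- array(rnorm(d * T_), c(d, T_, 1))
  got <- mha$fw(x, x)
  want <- naive_attention(t(x[, , 1]), t(x[, , 1]), t(x[, , 1]))$out
  expect_lt(max(abs(got[, , 1] - t(want))), 1e-6)
})

test_that("multi-head attention preserves shape, divides the width, and is
           permutation-equivariant without positional information", {
  set.seed(10)
  expect_error(gaitTFS:::nn_mha(10, 4), "divisible")
  mha <- gaitTFS:::nn_mha(16, 4)
  x <- array(rnorm(16 * 12 * 3), c(16, 12, 3))
  y <- mha$fw(x, x)
  expect_equal(dim(y), dim(x))
  expect_lt(max(abs(apply(mha$cache$P, 3, rowSums) - 1)), 1e-5)

  perm <- sample(12)
  y_perm <- mha$fw(x[, perm, , drop = FALSE], x[, perm, , drop = FALSE])
  expect_lt(max(abs(y_perm - y[, perm, , drop = FALSE])), 1e-8)
})

test_that("multi-channel attention matches a loop-built oracle on a
           hand-set single-channel input", {
  set.seed(12)
  mca <- gaitTFS:::nn_mca(1L, 2L)
  x <- array(rnorm(16), c(1, 4, 4, 1))
  got <- mca$fw(x, x)
  want <- naive_mca(array(x, c(1, 4, 4)),
                    mca$children$convq$par$W, mca$children$convq$par$b,
                    mca$children$convk$par$W, mca$children$convk$par$b,
                    mca$children$convv$par$W, mca$children$convv$par$b)
  expect_lt(max(abs(got[, , , 1] - want)), 1e-6)
  expect_equal(dim(got), c(2L, 4L, 4L, 1L))
  expect_lt(max(abs(apply(mca$cache$P, 3, rowSums) - 1)), 1e-5)
})

test_that("multi-channel attention on zero input with zero bias gives
           uniform attention and zero output", {
  set.seed(13)
  mca <- gaitTFS:::nn_mca(2L, 3L)
  x <- array(0, c(2, 8, 8, 2))
  y <- mca$fw(x, x)
  expect_equal(max(abs(y)), 0)
  expect_lt(max(abs(mca$cache$P - 1 / 8)), 1e-12)
})

test_that("the feed-forward stack matches the naive row-wise oracle", {
  set.seed(14)
  ffn <- gaitTFS:::nn_mlp(c(5, 7, 6, 5))
  x <- matrix(rnorm(20), 5)        # 4 tokens of width 5
  got <- ffn$fw(x)
  ch <- ffn$children
  want <- naive_ffn(t(x),
                    t(ch$lin1$par$W), ch$lin1$par$b,
                    t(ch$lin2$par$W), ch$lin2$par$b,
                    t(ch$lin3$par$W), ch$lin3$par$b)
  expect_lt(max(abs(got - t(want))), 1e-6)
})

test_that("the 2-D convolution kernel matches the naive loop oracle", {
  set.seed(15)
  l <- gaitTFS:::nn_conv2d(3L, 4L)
  x <- array(rnorm(3 * 5 * 5 * 2), c(3, 5, 5, 2))
  expect_lt(max(abs(l$fw(x) - naive_conv2d(x, l$par$W, l$par$b))), 1e-10)
})
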