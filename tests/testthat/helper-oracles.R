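# Independent naive-loop oracles for the network equations, plus small
# shared fixtures. Oracles deliberately avoid every code path they check.

# softmax(Q K' / sqrt(d_k)) V by explicit double loops
naive_attention <- function(Q, K, V, d_k = ncol(K)) {
  nq <- nrow(Q); nk <- nrow(K)
  S <- matrix(0, nq, nk)
  for (i in seq_len(nq)) {
    for (j in seq_len(nk)) {
      S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    }
  }
  P <- matrix(0, nq, nk)
  for (i in seq_len(nq)) P[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
  out <- matrix(0, nq, ncol(V))
  for (i in seq_len(nq)) {
    for (j in seq_len(ncol(V))) out[i, j] <- sum(P[i, ] * V[, j])
  }
  list(out = out, P = P)
}

# FFN(x) = relu(relu(x W1 + b1) W2 + b2) W3 + b3, rows of x independent
naive_ffn <- function(x, W1, b1, W2, b2, W3, b3) {
  relu <- function(z) pmax(z, 0)
  h1 <- relu(x %*% W1 + matrix(b1, nrow(x), length(b1), byrow = TRUE))
  h2 <- relu(h1 %*% W2 + matrix(b2, nrow(x), length(b2), byrow = TRUE))
  h2 %*% W3 + matrix(b3, nrow(x), length(b3), byrow = TRUE)
}

# sinusoidal positional encoding by direct per-element evaluation
naive_pe <- function(n_pos, d_model) {
  pe <- matrix(0, n_pos, d_model)
  for (pos in 0:(n_pos - 1)) {
    for (j in 0:(d_model - 1)) {
      i <- j %/% 2
      a <- pos / 10000^(2 * i / d_model)
      pe[pos + 1, j + 1] <- if (j %% 2 == 0) sin(a) else cos(a)
    }
  }
  pe
}

# padded stride-1 2-D convolution by quadruple loops; weight columns run
# over (input channel fastest, row offset, column offset)
naive_conv2d <- function(x, Wm, b, k = 3, pad = 1) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  c_out <- nrow(Wm)
  out <- array(0, c(c_out, H, W, B))
  for (bb in seq_len(B)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        col <- numeric(C * k * k)
        for (dj in seq_len(k)) {
          for (di in seq_len(k)) {
            ii <- i + di - 1 - pad; jj <- j + dj - 1 - pad
            if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
              col[(dj - 1) * k * C + (di - 1) * C + seq_len(C)] <-
                x[, ii, jj, bb]
            }
          }
        }
        out[, i, j, bb] <- Wm %*% col + b
      }
    }
  }
  out
}

# multi-channel attention on one (c_in, H, W) map by loops: conv Q/K/V then
# per output channel softmax(Qc Kc' / sqrt(W)) Vc
naive_mca <- function(x, Wq, bq, Wk, bk, Wv, bv) {
  d <- dim(x)
  x4 <- array(x, c(d, 1))
  Q <- naive_conv2d(x4, Wq, bq); K <- naive_conv2d(x4, Wk, bk)
  V <- naive_conv2d(x4, Wv, bv)
  c_out <- nrow(Wq); H <- d[2]; W <- d[3]
  out <- array(0, c(c_out, H, W))
  for (ch in seq_len(c_out)) {
    out[ch, , ] <- naive_attention(matrix(Q[ch, , , 1], H, W),
                                   matrix(K[ch, , , 1], H, W),
                                   matrix(V[ch, , , 1], H, W), W)$out
  }
  out
}

# dominant frequency (cycles/sample) as the positive-frequency FFT peak
fft_peak_freq <- function(x) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:(n %/% 2)]
  which.max(sp) / n
}

# amplitude of a known-frequency sinusoid by least-squares basis fit
fit_sine_amplitude <- function(x, freq_hz, fs) {
  t <- (seq_along(x) - 1) / fs
  b <- stats::lm(x ~ sin(2 * pi * freq_hz * t) + cos(2 * pi * freq_hz * t))
  sqrt(sum(stats::coef(b)[2:3]^2))
}

# independent forward kinematics of the sagittal two-link chain
oracle_forward_kinematics <- function(q1, q2, hip_x = 0, hip_z = 1,
                                      thigh = 0.42, shank = 0.4) {
  xk <- hip_x + thigh * sin(q1)
  zk <- hip_z - thigh * cos(q1)
  xa <- xk + shank * sin(q1 - q2)
  za <- zk - shank * cos(q1 - q2)
  c(hip_x, hip_z, xk, zk, xa, za)
}

# draw n poses inside the invertible domain of the plain-atan two-link
# model: |q1| < 1 and shank inclination |q1 - q2| below pi/2
draw_invertible_poses <- function(n) {
  q1 <- runif(n, -1, 1)
  q2 <- runif(n, -1, 1)
  while (any(bad <- abs(q1 - q2) >= 1.5)) {
    q2[bad] <- runif(sum(bad), -1, 1)
  }
  cbind(q1, q2)
}

# build a marker series in which every sample encodes one random pose
pose_marker_series <- function(q1l, q2l, q1r, q2r, thigh = 0.42,
                               shank = 0.4) {
  if (length(q1l) == 1L) {
    q1l <- rep(q1l, 2); q2l <- rep(q2l, 2)
    q1r <- rep(q1r, 2); q2r <- rep(q2r, 2)
  }
  n <- length(q1l)
  left <- t(mapply(function(a, b) {
    oracle_forward_kinematics(a, b, thigh = thigh, shank = shank)
  }, q1l, q2l))
  right <- t(mapply(function(a, b) {
    oracle_forward_kinematics(a, b, thigh = thigh, shank = shank)
  }, q1r, q2r))
  marker_series((seq_len(n) - 1) / 100, cbind(left, right))
}

# shared cache so expensive runs are computed once per test session
.gait_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (is.null(.gait_test_cache[[key]])) .gait_test_cache[[key]] <- fn()
  .gait_test_cache[[key]]
}

# the scaled-down learnability experiment shared by the acceptance tests
learnability_run <- function(master_seed = 7L) {
  ds <- cache_get("learn_ds", function() {
    cohort <- simulate_cohort(6, duration = 6, sampling_rate = 100,
                              master_seed = derive_seed(master_seed,
                                                        "simulate"))
    dataset_from_cohort(cohort, n = 32, k = 1,
                        seed = derive_seed(master_seed, "split"))
  })
  model <- build_tfsformer(model_config(k = 1, width_multiplier = 0.25),
                           seed = derive_seed(master_seed, "init"))
  fit <- train_model(model, ds,
                     train_config(max_epochs = 20,
                                  seed = derive_seed(master_seed, "train")))
  list(dataset = ds, fit = fit,
       report = evaluate_model(fit$model, ds),
       constant = constant_mean_report(ds))
}
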