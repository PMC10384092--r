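make_force <- function(mat, fs = 100) {
  force_series((seq_len(nrow(mat)) - 1) / fs, mat)
}

test_that("cubic-spline gap filling is exact on cubic signals and leaves
           valid samples untouched", {
  t <- 0:9
  y <- t^3
  mat <- matrix(rep(y, 6), 10)
  mat[5:6, 3] <- NA            # t = 4, 5 masked
  orig <- make_force(mat, fs = 1)
  fs <- fill_small_gaps(orig)
  expect_lt(max(abs(fs$series$data[5:6, 3] - y[5:6])), 1e-9)
  # bitwise equality outside the gap
  expect_identical(fs$series$data[-(5:6), ], orig$data[-(5:6), ])
  expect_identical(fs$series$data[, -3], orig$data[, -3])
  expect_equal(nrow(fs$report), 1L)
  expect_true(all(fs$report$filled))
})

test_that("runs longer than max_gap and boundary runs stay masked and are
           reported", {
  mat <- matrix(rnorm(300), 50)
  mat[10:15, 2] <- NA          # run of 6 > max_gap = 5
  mat[1:2, 4] <- NA            # boundary run
  fs <- fill_small_gaps(make_force(mat))
  expect_true(all(is.na(fs$series$data[10:15, 2])))
  expect_true(all(is.na(fs$series$data[1:2, 4])))
  expect_equal(sum(!fs$report$filled), 2L)

  clean <- make_force(matrix(rnorm(300), 50))
  out <- fill_small_gaps(clean)
  expect_identical(out$series$data, clean$data)
  expect_equal(nrow(out$report), 0L)
})

test_that("segment rejection splits on unfillable gaps and sustained
           outliers", {
  clean <- make_force(matrix(rnorm(600), 100))
  r <- reject_corrupt_segments(clean)
  expect_length(r$segments, 1L)
  expect_equal(nrow(r$log), 0L)

  gap <- clean
  gap$data[50, 3] <- NA
  r2 <- reject_corrupt_segments(gap)
  expect_length(r2$segments, 2L)
  expect_equal(r2$log$reason, "missing")

  # 20-sample saturation spike around z ~ 12 on one channel
  set.seed(3)
  spiky <- matrix(rnorm(1200), 200)
  spiky[101:120, 5] <- 12 * mad(spiky[, 5]) + median(spiky[, 5])
  r3 <- reject_corrupt_segments(make_force(spiky))
  expect_length(r3$segments, 2L)
  expect_true("noise" %in% r3$log$reason)
  kept <- do.call(c, lapply(r3$segments, function(s) s$time)) * 100 + 1
  expect_false(any(101:120 %in% round(kept)))

  allbad <- make_force(matrix(NA_real_, 30, 6))
  expect_error(reject_corrupt_segments(allbad), "no usable data")
})

test_that("zero-phase low-pass keeps DC and the pass band, kills the stop
           band, and is idempotent on band-limited input", {
  fs <- 1000
  t <- (0:2047) / fs
  const <- make_force(matrix(5, 2048, 6), fs)
  expect_lt(max(abs(lowpass_filter(const, 60)$data - 5)), 1e-9)

  x10 <- sin(2 * pi * 10 * t)
  x200 <- sin(2 * pi * 200 * t)
  mat <- cbind(x10, x200, x10, x200, x10, x200)
  filt <- lowpass_filter(make_force(mat, fs), 60)
  a10 <- fit_sine_amplitude(filt$data[, 1], 10, fs)
  a200 <- fit_sine_amplitude(filt$data[, 2], 200, fs)
  expect_gt(a10, 0.99)
  expect_lt(a10, 1.01)
  expect_lt(20 * log10(a200), -20)   # >= 20 dB attenuation

  twice <- lowpass_filter(filt, 60)
  a10b <- fit_sine_amplitude(twice$data[, 1], 10, fs)
  expect_lt(abs(a10b - a10) / a10, 0.01)

  expect_error(lowpass_filter(make_force(mat, fs), 600), "Nyquist")
})

test_that("moving-window division yields L - n - k + 1 contiguous windows", {
  L <- 40
  fm <- matrix(seq_len(L * 6), L)
  am <- matrix(seq_len(L * 4) / 100, L) / max(L * 4 / 100) * 3 - 1.5
  w1 <- make_windows(fm, am, n = 32, k = 1)
  expect_equal(dim(w1$inputs)[3], 8L)
  w6 <- make_windows(fm, am, n = 32, k = 6)
  expect_equal(dim(w6$inputs)[3], 3L)

  # contiguity: last input row of window i immediately precedes its first
  # target row in the source series
  expect_equal(w6$inputs[32, , 1], fm[32, ])
  expect_equal(w6$targets[1, , 1], am[33, ])
  expect_equal(w6$inputs[32, , 3], fm[34, ])
  expect_equal(w6$targets[1, , 3], am[35, ])

  expect_error(make_windows(fm[1:30, ], am[1:30, ], 32, 1), "too short")

  set.seed(11)
  for (rep in 1:20) {
    L <- sample(40:120, 1); n <- sample(4:32, 1)
    k <- sample(1:6, 1)
    if (L < n + k) next
    w <- make_windows(matrix(rnorm(L * 6), L), matrix(rnorm(L * 4) / 10, L),
                      n, k)
    expect_equal(dim(w$inputs)[3], L - n - k + 1L)
  }
})
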