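test_that("VMD returns zero modes for a zero signal", {
  r <- vmd_decompose(numeric(64), vmd_config(K = 3))
  expect_equal(max(abs(r$modes)), 0)
  expect_equal(r$residual, 0)
})

test_that("VMD recovers a single tone's centre frequency and waveform", {
  t <- 0:1023
  s <- sin(2 * pi * 0.05 * t)
  r <- vmd_decompose(s, vmd_config(K = 1))
  expect_lt(abs(r$omegas[1] - 0.05) / 0.05, 0.05)
  expect_gt(cor(r$modes[1, ], s), 0.99)
})

test_that("VMD separates two tones, sorted by ascending centre frequency,
           each mode peaking at its own frequency", {
  t <- 0:1023
  s <- sin(2 * pi * 0.03 * t) + sin(2 * pi * 0.15 * t)
  r <- vmd_decompose(s, vmd_config(K = 2))
  expect_equal(r$omegas, sort(r$omegas))
  oracle <- fft_peak_freq(s)                 # strongest component
  expect_lt(abs(r$omegas[1] - 0.03) / 0.03, 0.05)
  expect_lt(abs(r$omegas[2] - 0.15) / 0.15, 0.05)
  # each mode's own FFT peak sits at its reported centre frequency
  expect_lt(abs(fft_peak_freq(r$modes[1, ]) - r$omegas[1]), 0.01)
  expect_lt(abs(fft_peak_freq(r$modes[2, ]) - r$omegas[2]), 0.01)
  expect_true(is.finite(oracle))
})

test_that("VMD is homogeneous: scaling the input scales every mode", {
  t <- 0:255
  s <- sin(2 * pi * 0.04 * t) + 0.5 * sin(2 * pi * 0.2 * t)
  r1 <- vmd_decompose(s, vmd_config(K = 2))
  r3 <- vmd_decompose(3 * s, vmd_config(K = 2))
  expect_lt(max(abs(r3$modes - 3 * r1$modes)) / max(abs(r1$modes)), 1e-6)
})

test_that("dual-ascent variant reconstructs band-limited signals", {
  t <- 0:511
  s <- sin(2 * pi * 0.04 * t) + 0.7 * sin(2 * pi * 0.18 * t)
  r <- vmd_decompose(s, vmd_config(K = 2, tau = 0.5))
  expect_lt(r$residual, 0.05)
})

test_that("VMD rejects short or non-finite input", {
  expect_error(vmd_decompose(rnorm(8)), "length")
  expect_error(vmd_decompose(c(rnorm(31), NA)), "finite")
})

test_that("window decomposition is channel-independent with channel-major
           mode layout", {
  z <- matrix(0, 32, 6)
  out0 <- decompose_window(z)
  expect_equal(dim(out0), c(32L, 18L))
  expect_equal(max(abs(out0)), 0)

  one <- z
  one[, 4] <- sin(2 * pi * 0.2 * (0:31))
  out1 <- decompose_window(one)
  nz <- which(colSums(abs(out1)) > 1e-9)
  expect_true(all(nz %in% 10:12))            # channel 4 owns columns 10..12

  # two-tone channel: the low-frequency mode column is smoother than the
  # high-frequency one (smaller mean absolute first difference)
  two <- z
  two[, 1] <- sin(2 * pi * 0.05 * (0:31)) + sin(2 * pi * 0.3 * (0:31))
  out2 <- decompose_window(two, vmd_config(K = 2))
  tv <- function(x) mean(abs(diff(x)))
  expect_lt(tv(out2[, 1]), tv(out2[, 2]))
})
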