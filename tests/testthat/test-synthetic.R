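noiseless_spec <- function(id = "S01", period = 1.1) {
  subject_spec(id, period = period, weight = 700, a_hip = 0.35,
               a_knee = 1.05, thigh = 0.42, shank = 0.40,
               phase_jitter_sd = 0, noise_sd = 0)
}

test_that("noise-free forces vanish exactly throughout every swing phase", {
  sim <- simulate_subject(noiseless_spec(), duration = 10,
                          sampling_rate = 100, seed = 1)
  phi <- 2 * pi * sim$forces$time / 1.1
  swing_l <- (phi / (2 * pi)) %% 1 >= 0.6
  expect_equal(max(abs(sim$forces$data[swing_l, 1:3])), 0)
  swing_r <- ((phi + pi) / (2 * pi)) %% 1 >= 0.6
  expect_equal(max(abs(sim$forces$data[swing_r, 4:6])), 0)
})

test_that("inverse kinematics of the simulated markers recovers the
           generating angles", {
  sim <- simulate_subject(noiseless_spec(), duration = 8,
                          sampling_rate = 100, seed = 2)
  rec <- joint_angles_from_markers(sim$markers)
  expect_lt(max(abs(rec$data - sim$angles$data)), 1e-9)
})

test_that("the dominant vertical-force period matches the subject's gait
           cycle (autocorrelation oracle)", {
  fs <- 100; period <- 1.2
  sim <- simulate_subject(noiseless_spec(period = period), duration = 12,
                          sampling_rate = fs, seed = 3)
  f1z <- sim$forces$data[, "f1z"]
  ac <- stats::acf(f1z, lag.max = 200, plot = FALSE)$acf[-1]
  # first local maximum of the autocorrelation beyond half a cycle
  lo <- round(0.75 * period * fs)
  peak_lag <- lo - 1 + which.max(ac[lo:(lo + round(0.5 * period * fs))])
  expect_lte(abs(peak_lag - period * fs), 1)
})

test_that("left and right vertical forces are anti-phase: cross-correlation
           peaks half a cycle apart", {
  fs <- 100; period <- 1.0
  sim <- simulate_subject(noiseless_spec(period = period), duration = 12,
                          sampling_rate = fs, seed = 4)
  cc <- stats::ccf(sim$forces$data[, "f1z"], sim$forces$data[, "f2z"],
                   lag.max = 80, plot = FALSE)
  lags <- cc$lag[, 1, 1]
  sel <- abs(lags) <= round(0.75 * period * fs) & abs(lags) >= 1
  best <- lags[sel][which.max(cc$acf[sel, 1, 1])]
  expect_lte(abs(abs(best) - period * fs / 2), 1)
})

test_that("vertical-force peaks land at 1.1-1.2 body weight across a
           noiseless cohort", {
  cohort <- simulate_cohort(5, duration = 6, sampling_rate = 100,
                            master_seed = 5, noise_sd = 0,
                            phase_jitter_sd = 0)
  ratio <- vapply(cohort, function(sub) {
    max(sub$forces$data[, "f1z"]) / sub$spec$weight
  }, 0)
  expect_true(all(ratio > 1.1 & ratio < 1.2))
})

test_that("generate_dataset writes a reproducible cohort that reads back", {
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_dataset(4, duration = 4, sampling_rate = 100, master_seed = 9,
                   out_dir = d1)
  generate_dataset(4, duration = 4, sampling_rate = 100, master_seed = 9,
                   out_dir = d2)
  files <- list.files(d1)
  expect_length(grep("^markers_", files), 4L)
  expect_length(grep("^forces_", files), 4L)
  expect_true("manifest.json" %in% files)
  for (f in setdiff(files, "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_error(generate_dataset(4, duration = 4, master_seed = 9,
                                out_dir = d1), "overwrite")
  back <- read_dataset(d1)
  expect_length(back, 4L)
  expect_equal(dim(back[[1]]$forces$data), c(400L, 6L))
  # CSV round trip preserves values to the written precision
  orig <- simulate_cohort(4, duration = 4, sampling_rate = 100,
                          master_seed = 9)
  expect_lt(max(abs(back[[2]]$forces$data - orig[[2]]$forces$data)), 1e-6)
})

test_that("injected gaps are repaired by the preprocessing chain", {
  sim <- simulate_subject(noiseless_spec(), duration = 6,
                          sampling_rate = 100, seed = 6)
  gappy <- inject_gaps(sim$markers, n_gaps = 6, max_len = 4, seed = 7)
  expect_gt(sum(gappy$mask), 0)
  fixed <- fill_small_gaps(gappy, max_gap = 5)
  expect_equal(sum(fixed$series$mask), 0L)
  # spline repair of marker curves is sub-millimetre
  expect_lt(max(abs(fixed$series$data - sim$markers$data)), 1e-3)
})

test_that("simulator preconditions are enforced", {
  expect_error(subject_spec("x", stance_frac = 1.2), "stance_frac")
  expect_error(simulate_subject(noiseless_spec(period = 1.2), duration = 2),
               "3 gait cycles")
  expect_error(simulate_cohort(3), "at least 4")
})
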