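tiny_dataset <- function(k = 1L) {
  cache_get(paste0("tiny_ds_k", k), function() {
    cohort <- simulate_cohort(4, duration = 4, sampling_rate = 100,
                              master_seed = 21)
    dataset_from_cohort(cohort, n = 32, k = k, seed = 21)
  })
}

test_that("the subject split holds out whole subjects and keeps the 8:2
           ratio", {
  ids <- rep(sprintf("S%02d", 1:35), each = 50)
  sp <- split_dataset(ids, seed = 4)
  expect_length(sp$test_subjects, 3L)
  expect_setequal(unique(ids[sp$test]), sp$test_subjects)
  expect_false(any(ids[c(sp$train, sp$val)] %in% sp$test_subjects))
  expect_length(intersect(sp$train, sp$val), 0L)
  ratio <- length(sp$val) / (length(sp$train) + length(sp$val))
  expect_lt(abs(ratio - 0.2), 32 / (32 * 50))   # within one batch

  sp2 <- split_dataset(ids, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_dataset(rep(c("a", "b", "c"), 10)), "at least 4")
})

test_that("metrics follow their definition: zero for perfect prediction,
           offset and offset squared for a constant bias", {
  set.seed(2)
  targ <- array(runif(3 * 4 * 7, -1, 1), c(3, 4, 7))
  r0 <- metric_report(targ, targ)
  expect_equal(unname(r0$mae), rep(0, 5))
  expect_equal(unname(r0$mse), rep(0, 5))
  roff <- metric_report(targ + 0.1, targ)
  expect_equal(unname(roff$mae), rep(0.1, 5), tolerance = 1e-12)
  expect_equal(unname(roff$mse), rep(0.01, 5), tolerance = 1e-12)
})

test_that("metrics on a hand-written 3-window table match the manual
           spreadsheet computation", {
  # k = 1, three windows; channels (q1 lhip, q2 lknee, q3 rhip, q4 rknee)
  pred <- array(c(0.10, 0.50, -0.20, 0.40,
                  0.00, 0.80, 0.10, -0.30,
                  -0.05, 0.25, 0.35, 0.15), c(1, 4, 3))
  true <- array(c(0.12, 0.45, -0.25, 0.52,
                  -0.04, 0.70, 0.02, -0.21,
                  0.00, 0.30, 0.30, 0.06), c(1, 4, 3))
  r <- metric_report(pred, true)
  # manual per-joint absolute errors
  e1 <- c(0.02, 0.04, 0.05)        # q1 (Hl)
  e2 <- c(0.05, 0.10, 0.05)        # q2 (Kl)
  e3 <- c(0.05, 0.08, 0.05)        # q3 (Hr)
  e4 <- c(0.12, 0.09, 0.09)        # q4 (Kr)
  expect_equal(r$mae[["Hl"]], mean(e1), tolerance = 1e-12)
  expect_equal(r$mae[["Kl"]], mean(e2), tolerance = 1e-12)
  expect_equal(r$mae[["Hr"]], mean(e3), tolerance = 1e-12)
  expect_equal(r$mae[["Kr"]], mean(e4), tolerance = 1e-12)
  expect_equal(r$mse[["Hl"]], mean(e1^2), tolerance = 1e-12)
  expect_equal(r$mse[["Kr"]], mean(e4^2), tolerance = 1e-12)
  # the M row is the arithmetic mean of the four per-joint rows
  expect_equal(r$mae[["M"]], mean(r$mae[c("Hl", "Hr", "Kl", "Kr")]),
               tolerance = 1e-12)
  expect_equal(r$mse[["M"]], mean(r$mse[c("Hl", "Hr", "Kl", "Kr")]),
               tolerance = 1e-12)
})

test_that("a short training run finishes with finite decreasing loss", {
  ds <- tiny_dataset()
  m <- build_tfsformer(model_config(k = 1, width_multiplier = 0.25),
                       seed = 11)
  fit <- train_model(m, ds, train_config(max_epochs = 2, seed = 11))
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_equal(fit$epochs_run, 2L)
  expect_lt(fit$history$train_loss[1], fit$initial_loss)
})

test_that("training rejects a model whose horizon disagrees with the
           dataset", {
  ds <- tiny_dataset()
  m <- build_tfsformer(model_config(k = 3, width_multiplier = 0.25),
                       seed = 12)
  expect_error(train_model(m, ds), "does not match")
})

test_that("checkpoints round-trip parameters, statistics and predictions", {
  ds <- tiny_dataset()
  m <- build_tfsformer(model_config(k = 1, width_multiplier = 0.25),
                       seed = 13)
  fit <- train_model(m, ds, train_config(max_epochs = 1, seed = 13))
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(fit$model, path, seed = 13)
  m2 <- load_checkpoint(path)
  idx <- ds$split$test[1:8]
  p1 <- gaitTFS:::predict_batched(fit$model, ds$x, ds$vmd, idx)
  p2 <- gaitTFS:::predict_batched(m2, ds$x, ds$vmd, idx)
  expect_identical(p1, p2)
  expect_equal(m2$stats, fit$model$stats)
})

test_that("evaluation refuses an empty test set", {
  ds <- tiny_dataset()
  m <- build_tfsformer(model_config(k = 1, width_multiplier = 0.25),
                       seed = 14)
  expect_error(evaluate_model(m, ds, idx = integer()), "empty")
})
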