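## Dataset partitioning, the optimisation loop shared by all four models,
## and the evaluation metrics.

#' Training configuration
#'
#' @param batch_size minibatch size (32 in the reference setup).
#' @param lr initial AdamW learning rate (1e-4).
#' @param weight_decay decoupled weight decay (0.01; not applied to biases
#'   or normalisation parameters).
#' @param max_epochs epoch cap (default 100).
#' @param patience early-stopping patience on validation MAE (default 10).
#' @param seed integer seed governing initialisation shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, lr = 1e-4, weight_decay = 0.01,
                         max_epochs = 100L, patience = 10L, seed = 1L) {
  stopifnot(batch_size >= 1L, lr > 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Subject-aware train/validation/test partition
#'
#' Puts `n_test` whole subjects aside as the test set (no window of a test
#' subject ever appears in training), then splits the remaining windows
#' 8:2 into training and validation. The split is a pure function of
#' `seed`.
#'
#' @param subject_ids character/factor vector, one entry per window.
#' @param seed integer seed.
#' @param n_test number of held-out test subjects (default 3).
#' @param val_frac validation fraction of the non-test windows (default
#'   0.2).
#' @return A list with integer index vectors `train`, `val`, `test` and
#'   `test_subjects`.
#' @export
split_dataset <- function(subject_ids, seed = 1L, n_test = 3L,
                          val_frac = 0.2) {
  subjects <- unique(subject_ids)
  if (length(subjects) < n_test + 1L) {
    stop("need at least ", n_test + 1L, " subjects, got ", length(subjects))
  }
  set.seed(derive_seed(seed, "split"))
  test_subjects <- sample(subjects, n_test)
  test <- which(subject_ids %in% test_subjects)
  rest <- which(!(subject_ids %in% test_subjects))
  rest <- rest[sample.int(length(rest))]
  nval <- round(val_frac * length(rest))
  list(train = sort(rest[-seq_len(nval)]),
       val = sort(rest[seq_len(nval)]),
       test = sort(test),
       test_subjects = test_subjects)
}

#' Assemble a supervised dataset from a simulated (or loaded) cohort
#'
#' Runs the preprocessing chain per subject (inverse kinematics from the
#' markers, optional low-pass filtering of the forces, moving-window
#' division), splits by subject, computes per-channel standardisation
#' statistics on the training windows only, and attaches the VMD blocks of
#' the standardised forces: with `vmd_scope = "session"` each subject's
#' force series is decomposed once and the mode series windowed alongside
#' the forces; with `"window"` every 32-sample window is decomposed
#' independently.
#'
#' @param cohort list of per-subject lists with `markers` and `forces`
#'   (from [simulate_cohort()] or [read_dataset()]); subject ids are taken
#'   from spec/manifest entries or positional.
#' @param n,k window length and prediction horizon.
#' @param vmd a [vmd_config()].
#' @param vmd_scope `"session"` or `"window"`.
#' @param seed split seed.
#' @param n_test,val_frac passed to [split_dataset()].
#' @param lowpass_cutoff optional low-pass cut-off in Hz applied to the
#'   forces before windowing (must stay below Nyquist).
#' @return A list of class `gait_dataset` with `x` (`n x 6 x N` raw force
#'   windows), `vmd` (`n x 6K x N`), `targets` (`k x 4 x N`), `subject`,
#'   `split`, `stats` and bookkeeping fields.
#' @export
dataset_from_cohort <- function(cohort, n = 32L, k = 1L,
                                vmd = vmd_config(),
                                vmd_scope = c("session", "window"),
                                seed = 1L, n_test = 3L, val_frac = 0.2,
                                lowpass_cutoff = NULL) {
  vmd_scope <- match.arg(vmd_scope)
  n <- as.integer(n); k <- as.integer(k)
  per <- lapply(seq_along(cohort), function(i) {
    sub <- cohort[[i]]
    id <- sub$spec$subject_id %||% sub$spec_info$subject_id %||%
      sprintf("S%02d", i)
    forces <- sub$forces
    if (!is.null(lowpass_cutoff)) {
      forces <- lowpass_filter(forces, lowpass_cutoff)
    }
    angles <- joint_angles_from_markers(sub$markers)
    w <- make_windows(forces, angles, n, k)
    list(id = id, w = w, force_mat = forces$data)
  })
  counts <- vapply(per, function(p) dim(p$w$inputs)[3], 1L)
  N <- sum(counts)
  x <- array(0, c(n, 6L, N))
  targets <- array(0, c(k, 4L, N))
  subject <- character(N)
  off <- 0L
  for (p in per) {
    idx <- off + seq_len(dim(p$w$inputs)[3])
    x[, , idx] <- p$w$inputs
    targets[, , idx] <- p$w$targets
    subject[idx] <- p$id
    off <- off + length(idx)
  }
  split <- split_dataset(subject, seed, n_test, val_frac)
  mu <- vapply(1:6, function(c) mean(x[, c, split$train]), 0)
  sd_ <- vapply(1:6, function(c) stats::sd(as.vector(x[, c, split$train])), 0)
  sd_[sd_ < 1e-12] <- 1
  stats_ <- list(mu = mu, sd = sd_)

  vwidth <- 6L * vmd$K
  vmdx <- array(0, c(n, vwidth, N))
  if (vmd_scope == "session") {
    off <- 0L
    for (p in per) {
      z <- sweep(sweep(p$force_mat, 2L, mu), 2L, sd_, "/")
      modes <- vmd_series(z, vmd)
      nw <- dim(p$w$inputs)[3]
      for (i in seq_len(nw)) {
        vmdx[, , off + i] <- modes[i:(i + n - 1L), ]
      }
      off <- off + nw
    }
  } else {
    xn <- standardize_windows(x, stats_)
    for (i in seq_len(N)) {
      vmdx[, , i] <- decompose_window(xn[, , i], vmd)
    }
  }
  structure(list(x = x, vmd = vmdx, targets = targets, subject = subject,
                 split = split, stats = stats_, n = n, k = k,
                 vmd_config = vmd, vmd_scope = vmd_scope),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf(
    "<gait_dataset> %d windows (n = %d, k = %d), %d subjects; train/val/test = %d/%d/%d\n",
    dim(x$x)[3], x$n, x$k, length(unique(x$subject)),
    length(x$split$train), length(x$split$val), length(x$split$test)))
  invisible(x)
}

## Batched eval-mode prediction; returns a (k*4, N) matrix.
predict_batched <- function(model, x, v, idx, batch_size = 64L) {
  k4 <- model$config$k * 4L
  out <- matrix(0, k4, length(idx))
  off <- 0L
  while (off < length(idx)) {
    ids <- idx[(off + 1L):min(off + batch_size, length(idx))]
    vb <- if (is.null(v)) NULL else v[, , ids, drop = FALSE]
    out[, off + seq_along(ids)] <-
      model$fw(x[, , ids, drop = FALSE], vb, train = FALSE)
    off <- off + length(ids)
  }
  out
}

#' Train a model with AdamW on mean absolute error
#'
#' Minimises the MAE between predicted and target angle blocks with AdamW
#' (decoupled weight decay), early-stops on validation MAE with the
#' configured patience, and restores the best-validation parameters before
#' returning. All four architectures train through this one harness with
#' identical hyperparameters.
#'
#' @param model a model from [build_tfsformer()] or [build_baseline()].
#' @param dataset a `gait_dataset` from [dataset_from_cohort()].
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return A list with the trained `model`, `history` (per-epoch train
#'   loss and validation MAE), `initial_loss` (training loss of the
#'   untrained model), `best_val` and `epochs_run`.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(dataset, "gait_dataset"))
  if (model$config$k != dataset$k) {
    stop("model k (", model$config$k, ") does not match dataset k (",
         dataset$k, ")")
  }
  model$stats <- dataset$stats
  x <- dataset$x
  v <- if (model$needs_vmd %||% TRUE) dataset$vmd else NULL
  ym <- matrix(dataset$targets, dataset$k * 4L)
  tr <- dataset$split$train
  va <- dataset$split$val
  if (length(tr) == 0L || length(va) == 0L) stop("empty train or val split")

  set.seed(derive_seed(config$seed, "train"))
  opt <- adamw_new(model, lr = config$lr, weight_decay = config$weight_decay)
  initial_loss <- mae_loss(predict_batched(model, x, v, tr), ym[, tr,
                                                               drop = FALSE])$value
  best_val <- Inf
  best_par <- NULL
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = double(),
                     val_mae = double())
  for (epoch in seq_len(config$max_epochs)) {
    perm <- tr[sample.int(length(tr))]
    tot <- 0
    nb <- 0L
    off <- 0L
    while (off < length(perm)) {
      ids <- perm[(off + 1L):min(off + config$batch_size, length(perm))]
      vb <- if (is.null(v)) NULL else v[, , ids, drop = FALSE]
      pred <- model$fw(x[, , ids, drop = FALSE], vb, train = TRUE)
      l <- mae_loss(pred, ym[, ids, drop = FALSE])
      if (!is.finite(l$value)) {
        stop("NaN/Inf loss at epoch ", epoch, ", batch ", nb + 1L,
             " (lr = ", config$lr, ")")
      }
      zero_grads(model)
      model$bw(l$grad)
      adamw_step(opt)
      tot <- tot + l$value * length(ids)
      nb <- nb + 1L
      off <- off + length(ids)
    }
    val_mae <- mae_loss(predict_batched(model, x, v, va),
                        ym[, va, drop = FALSE])$value
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = tot / length(perm),
                                   val_mae = val_mae))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      tot / length(perm), val_mae))
    }
    if (val_mae < best_val - 1e-12) {
      best_val <- val_mae
      best_par <- get_params(model)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  if (!is.null(best_par)) set_params(model, best_par)
  list(model = model, history = hist, initial_loss = initial_loss,
       best_val = best_val, epochs_run = nrow(hist))
}

#' Per-joint MAE/MSE metric report
#'
#' Computes, for each of the four joints (left hip `Hl`, right hip `Hr`,
#' left knee `Kl`, right knee `Kr`), the mean absolute and mean squared
#' prediction error over all test windows (and, for multi-step tasks, over
#' the k prediction steps), plus their arithmetic mean `M`.
#'
#' @param pred,target `k x 4 x N` arrays of predicted and true angle
#'   blocks, channels ordered (left hip, left knee, right hip, right
#'   knee), radians.
#' @return A list of class `metric_report` with named `mae` and `mse`
#'   vectors over `(Hl, Hr, Kl, Kr, M)`.
#' @export
metric_report <- function(pred, target) {
  stopifnot(all(dim(pred) == dim(target)))
  if (length(dim(pred)) == 2L) {
    dim(pred) <- c(dim(pred), 1L)
    dim(target) <- dim(pred)
  }
  if (dim(pred)[3] == 0L) stop("empty test set")
  err <- pred - target
  joint_idx <- c(Hl = 1L, Hr = 3L, Kl = 2L, Kr = 4L)
  mae <- vapply(joint_idx, function(j) mean(abs(err[, j, ])), 0)
  mse <- vapply(joint_idx, function(j) mean(err[, j, ]^2), 0)
  mae <- c(mae, M = mean(mae))
  mse <- c(mse, M = mean(mse))
  structure(list(mae = mae, mse = mse), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  m <- rbind(MAE = x$mae, MSE = x$mse)
  print(round(m, 5))
  invisible(x)
}

#' Evaluate a trained model on a dataset partition
#'
#' @param model a trained model.
#' @param dataset a `gait_dataset`.
#' @param idx window indices to evaluate (defaults to the test partition).
#' @return A [metric_report()].
#' @export
evaluate_model <- function(model, dataset, idx = dataset$split$test) {
  if (length(idx) == 0L) stop("empty test set")
  v <- if (model$needs_vmd %||% TRUE) dataset$vmd else NULL
  pred <- predict_batched(model, dataset$x, v, idx)
  metric_report(array(pred, c(dataset$k, 4L, length(idx))),
                dataset$targets[, , idx, drop = FALSE])
}

#' Constant-mean predictor reference
#'
#' Predicts, for every test window, the training-set mean angle per joint
#' and step; the weakest sensible reference against which any trained
#' model is compared.
#'
#' @param dataset a `gait_dataset`.
#' @param idx evaluation indices (defaults to the test partition).
#' @return A [metric_report()].
#' @export
constant_mean_report <- function(dataset, idx = dataset$split$test) {
  tr_mean <- apply(dataset$targets[, , dataset$split$train, drop = FALSE],
                   c(1, 2), mean)
  pred <- array(tr_mean, c(dim(tr_mean), length(idx)))
  metric_report(pred, dataset$targets[, , idx, drop = FALSE])
}

## ------------------------------------------------------------ checkpoints

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the architecture
#' configuration, all parameters, the standardisation statistics, the VMD
#' configuration, the seed it was trained with and a format version.
#'
#' @param model a model object.
#' @param path file path.
#' @param seed the training seed to record.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns a rebuilt model.
#' @export
save_checkpoint <- function(model, path, seed = NA_integer_) {
  obj <- list(version = 1L, kind = model$kind, config = model$config,
              stats = model$stats, vmd = model$vmd, seed = seed,
              params = get_params(model))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version)) stop("checkpoint has no version field")
  model <- if (obj$kind == "tfsformer") {
    build_tfsformer(obj$config, stats = obj$stats,
                    vmd = obj$vmd %||% vmd_config())
  } else {
    build_baseline(obj$kind, obj$config, stats = obj$stats)
  }
  set_params(model, obj$params)
  model
}
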