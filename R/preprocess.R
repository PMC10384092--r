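## Time-series containers and the preprocessing chain: two-link inverse
## kinematics, cubic-spline gap filling, corrupt-segment rejection,
## zero-phase low-pass filtering and moving-window division.

marker_cols <- c("l_hip_x", "l_hip_z", "l_knee_x", "l_knee_z",
                 "l_ankle_x", "l_ankle_z",
                 "r_hip_x", "r_hip_z", "r_knee_x", "r_knee_z",
                 "r_ankle_x", "r_ankle_z")
force_cols <- c("f1x", "f1y", "f1z", "f2x", "f2y", "f2z")
angle_cols <- c("q1", "q2", "q3", "q4")

check_time <- function(time) {
  if (length(time) < 2L || any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("time must be finite and strictly increasing")
  }
  dt <- diff(time)
  if ((max(dt) - min(dt)) / mean(dt) > 1e-6) {
    stop("time step must be (approximately) constant")
  }
  invisible(1 / mean(dt))
}

new_channel_series <- function(time, data, cols, cls) {
  data <- as.matrix(data)
  rate <- check_time(time)
  if (ncol(data) != length(cols)) {
    stop("expected ", length(cols), " channels (", paste(cols, collapse = ","),
         "), got ", ncol(data))
  }
  if (nrow(data) != length(time)) stop("time and data lengths differ")
  colnames(data) <- cols
  structure(list(time = as.numeric(time), data = data,
                 sampling_rate = rate, mask = !is.finite(data)),
            class = c(cls, "channel_series"))
}

#' Sagittal marker series
#'
#' Time-indexed sagittal (x, z) hip/knee/ankle marker coordinates per leg.
#' Non-finite entries are treated as missing and tracked in a mask.
#'
#' @param time strictly increasing sample times in seconds with an
#'   (approximately) constant step.
#' @param data numeric matrix or data frame with the 12 columns
#'   `l_hip_x, l_hip_z, l_knee_x, l_knee_z, l_ankle_x, l_ankle_z` and the
#'   right-leg equivalents, in length units (m or mm, as acquired).
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(time, data) {
  new_channel_series(time, data, marker_cols, "marker_series")
}

#' Bilateral plantar force series
#'
#' Six channels `(f1x, f1y, f1z, f2x, f2y, f2z)` in Newtons: the three-axis
#' plantar force of the left foot followed by the right foot.
#'
#' @inheritParams marker_series
#' @param data numeric matrix with the six force columns.
#' @return An object of class `force_series`.
#' @export
force_series <- function(time, data) {
  new_channel_series(time, data, force_cols, "force_series")
}

#' Bilateral hip/knee joint-angle series
#'
#' Four channels `(q1, q2, q3, q4)` in radians: left hip, left knee, right
#' hip, right knee, flexion positive. Every angle must satisfy `|q| < pi`.
#'
#' @inheritParams marker_series
#' @param data numeric matrix with four angle columns.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(time, data) {
  x <- new_channel_series(time, data, angle_cols, "angle_series")
  if (any(abs(x$data) >= pi, na.rm = TRUE)) {
    stop("joint angles must satisfy |q| < pi (radians expected)")
  }
  x
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<%s> %d samples x %d channels @ %.6g Hz\n", class(x)[1],
              nrow(x$data), ncol(x$data), x$sampling_rate))
  nmiss <- sum(x$mask)
  if (nmiss > 0) cat("  missing entries:", nmiss, "\n")
  invisible(x)
}

## ------------------------------------------------------ inverse kinematics

two_link_angles <- function(xh, zh, xk, zk, xa, za, eps = 1e-9) {
  dz1 <- zh - zk
  dz2 <- zk - za
  bad1 <- abs(dz1) < eps
  bad2 <- abs(dz2) < eps
  if (any(bad1 | bad2)) {
    stop("degenerate posture (zero link drop) at sample index ",
         which(bad1 | bad2)[1], call. = FALSE)
  }
  q1 <- atan((xk - xh) / dz1)
  q2 <- q1 - atan((xa - xk) / dz2)
  cbind(q1, q2)
}

#' Joint angles from sagittal markers (two-link inverse kinematics)
#'
#' Treats thigh and shank as rigid links in the sagittal plane and recovers,
#' per leg, the hip angle `q1 = atan((xk - xh) / (zh - zk))` and the knee
#' angle `q2 = q1 - atan((xa - xk) / (zk - za))`, flexion positive with x
#' forward and z up. Plain `atan` is used, so postures beyond +/- pi/2 of
#' segment inclination are outside the supported range; a vanishing vertical
#' drop of either link raises a degenerate-posture error naming the sample.
#'
#' @param markers a [marker_series()] with all gaps already filled or
#'   rejected (any non-finite coordinate is an error).
#' @return An [angle_series()] with channels `(q1, q2, q3, q4)` = (left hip,
#'   left knee, right hip, right knee), in radians.
#' @export
#' @examples
#' t <- seq(0, 0.04, by = 0.01)
#' m <- matrix(rep(c(0, 1, 0, 0.5, 0, 0), each = 5), 5, 12)
#' colnames(m) <- NULL
#' ang <- joint_angles_from_markers(marker_series(t, cbind(m[, 1:6], m[, 1:6])))
#' ang$data[1, ]  # vertical limb: all zero
joint_angles_from_markers <- function(markers) {
  stopifnot(inherits(markers, "marker_series"))
  d <- markers$data
  if (any(!is.finite(d))) {
    stop("markers contain non-finite coordinates; fill or reject gaps first")
  }
  left <- two_link_angles(d[, "l_hip_x"], d[, "l_hip_z"],
                          d[, "l_knee_x"], d[, "l_knee_z"],
                          d[, "l_ankle_x"], d[, "l_ankle_z"])
  right <- two_link_angles(d[, "r_hip_x"], d[, "r_hip_z"],
                           d[, "r_knee_x"], d[, "r_knee_z"],
                           d[, "r_ankle_x"], d[, "r_ankle_z"])
  angle_series(markers$time,
               cbind(left[, 1], left[, 2], right[, 1], right[, 2]))
}

## Forward kinematics of the same two-link chain; the exact inverse of
## joint_angles_from_markers for |q1| < pi/2 and |q1 - q2| < pi/2.
two_link_forward <- function(q1, q2, hip_x, hip_z, thigh, shank) {
  xk <- hip_x + thigh * sin(q1)
  zk <- hip_z - thigh * cos(q1)
  th <- q1 - q2
  xa <- xk + shank * sin(th)
  za <- zk - shank * cos(th)
  cbind(hip_x, hip_z, xk, zk, xa, za)
}

## ------------------------------------------------------------- gap filling

runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

#' Fill short missing runs by cubic-spline interpolation
#'
#' Every masked (non-finite) run of length at most `max_gap` is replaced,
#' per channel, by cubic-spline values fitted through the channel's valid
#' samples; longer runs and runs touching the sequence boundary (which have
#' no bracketing support and would require extrapolation) are left masked
#' and reported. Valid samples are never altered.
#'
#' @param series a [marker_series()] or [force_series()].
#' @param max_gap longest run of missing samples that will be filled
#'   (default 5).
#' @return A list with `series` (same class, gaps filled) and `report`, a
#'   data frame with one row per missing run (`channel`, `start`, `length`,
#'   `filled`).
#' @export
fill_small_gaps <- function(series, max_gap = 5L) {
  stopifnot(inherits(series, "channel_series"))
  d <- series$data
  n <- nrow(d)
  rep_rows <- list()
  for (j in seq_len(ncol(d))) {
    miss <- !is.finite(d[, j])
    if (!any(miss)) next
    runs <- runs_of(miss)
    ok <- sum(!miss) >= 4L
    sf <- if (ok) {
      stats::splinefun(series$time[!miss], d[!miss, j], method = "fmm")
    } else NULL
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; len <- runs$length[i]
      boundary <- s == 1L || (s + len - 1L) == n
      fill <- ok && !boundary && len <= max_gap
      if (fill) d[s:(s + len - 1L), j] <- sf(series$time[s:(s + len - 1L)])
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(channel = colnames(d)[j], start = s, length = len,
                   filled = fill)
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(channel = character(), start = integer(), length = integer(),
               filled = logical())
  out <- series
  out$data <- d
  out$mask <- !is.finite(d)
  list(series = out, report = report)
}

## -------------------------------------------------------segment rejection

#' Split a series into clean segments, rejecting corrupt spans
#'
#' A sample is rejected when it is still missing after gap filling
#' (unfillable gap) or when any channel's robust z-score (deviation from the
#' channel median in median-absolute-deviation units) exceeds
#' `policy$z_max` for at least `policy$sustain` consecutive samples. The
#' remaining samples are returned as contiguous clean segments, each at
#' least `policy$min_length` samples long; every rejection is logged.
#'
#' @param series a [marker_series()] or [force_series()].
#' @param policy list with `z_max` (default 8), `sustain` (default 10
#'   samples) and `min_length` (default 2; shorter leftover fragments are
#'   dropped and logged).
#' @return A list with `segments` (list of series of the input class) and
#'   `log` (data frame `start`, `end`, `reason`).
#' @export
reject_corrupt_segments <- function(series,
                                    policy = list(z_max = 8, sustain = 10L,
                                                  min_length = 2L)) {
  stopifnot(inherits(series, "channel_series"))
  z_max <- policy$z_max %||% 8
  sustain <- policy$sustain %||% 10L
  min_length <- policy$min_length %||% 2L
  d <- series$data
  n <- nrow(d)
  bad <- rowSums(!is.finite(d)) > 0L
  reason <- ifelse(bad, "missing", NA_character_)
  for (j in seq_len(ncol(d))) {
    x <- d[, j]
    fin <- is.finite(x)
    if (sum(fin) < 8L) next
    med <- stats::median(x[fin])
    s <- stats::mad(x[fin])
    if (s == 0) s <- stats::sd(x[fin])
    if (!is.finite(s) || s == 0) next
    high <- abs(x - med) / s > z_max
    high[!fin] <- FALSE
    runs <- runs_of(high)
    runs <- runs[runs$length >= sustain, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      idx <- runs$start[i]:(runs$start[i] + runs$length[i] - 1L)
      bad[idx] <- TRUE
      reason[idx] <- ifelse(is.na(reason[idx]), "noise", reason[idx])
    }
  }
  log_rows <- list()
  if (any(bad)) {
    runs <- runs_of(bad)
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; e <- s + runs$length[i] - 1L
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(start = s, end = e,
                   reason = reason[s])
    }
  }
  segments <- list()
  good_runs <- runs_of(!bad)
  for (i in seq_len(nrow(good_runs))) {
    s <- good_runs$start[i]; len <- good_runs$length[i]
    if (len < max(2L, min_length)) {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(start = s, end = s + len - 1L, reason = "short_fragment")
      next
    }
    idx <- s:(s + len - 1L)
    seg <- series
    seg$time <- series$time[idx]
    seg$data <- d[idx, , drop = FALSE]
    seg$mask <- seg$mask[idx, , drop = FALSE]
    segments[[length(segments) + 1L]] <- seg
  }
  if (length(segments) == 0L) stop("no usable data after segment rejection")
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(start = integer(), end = integer(), reason = character())
  list(segments = segments, log = log)
}

## --------------------------------------------------------------- filtering

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`)
#' per channel, so the pass band keeps unit gain and zero phase: filtering
#' never shifts the force/angle alignment. Length and DC level are
#' preserved.
#'
#' @param series a `channel_series` (or plain numeric matrix with one
#'   channel per column).
#' @param cutoff_hz cut-off frequency in Hz (default 60, the acquisition
#'   denoising cut-off; requires `sampling_rate > 2 * cutoff_hz`).
#' @param sampling_rate sampling rate in Hz; taken from the series when
#'   omitted.
#' @return The filtered series (same class as the input).
#' @export
lowpass_filter <- function(series, cutoff_hz = 60, sampling_rate = NULL) {
  mat <- if (inherits(series, "channel_series")) series$data else
    as.matrix(series)
  fs <- sampling_rate %||%
    (if (inherits(series, "channel_series")) series$sampling_rate else
       stop("sampling_rate required for a plain matrix"))
  if (cutoff_hz >= fs / 2) {
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  }
  if (any(!is.finite(mat))) stop("filter input must be finite; fill gaps first")
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  ## odd-symmetric edge extension so the forward-backward pass starts from
  ## a decayed state; without it the zero initial conditions leak step
  ## transients into both ends
  L <- nrow(mat)
  npad <- min(L - 1L, max(200L, 10L * ceiling(fs / cutoff_hz)))
  out <- apply(mat, 2L, function(x) {
    ext <- c(2 * x[1] - x[(npad + 1L):2],
             x,
             2 * x[L] - x[(L - 1L):(L - npad)])
    y <- signal::filtfilt(bf, ext)
    y[(npad + 1L):(npad + L)]
  })
  if (inherits(series, "channel_series")) {
    series$data[] <- out
    series
  } else out
}

## -------------------------------------------------------------- windowing

#' Moving-window division into supervised samples
#'
#' Cuts a time-aligned force/angle pair into overlapping stride-1 windows:
#' window `i` (1-based) takes force samples `i .. i+n-1` as input and the
#' immediately following angle samples `i+n .. i+n+k-1` as target, so the
#' input block always abuts the target block with no gap. A series of
#' length `L` yields exactly `L - n - k + 1` windows.
#'
#' @param force a [force_series()] (or `L x 6` matrix).
#' @param angles an [angle_series()] (or `L x 4` matrix) sampled on the same
#'   clock; when both are series their timestamps must agree to within half
#'   a sample period.
#' @param n input window length in samples (32 in the reference setup).
#' @param k prediction horizon in samples (1, 3 or 6).
#' @return A list of class `windowed_samples` with `inputs` (`n x 6 x N`),
#'   `targets` (`k x 4 x N`) and `start` (window start indices).
#' @export
make_windows <- function(force, angles, n = 32L, k = 1L) {
  fm <- if (inherits(force, "force_series")) force$data else as.matrix(force)
  am <- if (inherits(angles, "angle_series")) angles$data else as.matrix(angles)
  if (inherits(force, "force_series") && inherits(angles, "angle_series")) {
    if (length(force$time) != length(angles$time) ||
        max(abs(force$time - angles$time)) > 0.5 / force$sampling_rate) {
      stop("force and angle series are not time-aligned")
    }
  }
  L <- nrow(fm)
  if (nrow(am) != L) stop("force and angle series lengths differ")
  n <- as.integer(n); k <- as.integer(k)
  if (L < n + k) {
    stop("series too short: length ", L, " < n + k = ", n + k)
  }
  N <- L - n - k + 1L
  inputs <- array(0, c(n, ncol(fm), N))
  targets <- array(0, c(k, ncol(am), N))
  for (i in seq_len(N)) {
    inputs[, , i] <- fm[i:(i + n - 1L), ]
    targets[, , i] <- am[(i + n):(i + n + k - 1L), , drop = FALSE]
  }
  structure(list(inputs = inputs, targets = targets, start = seq_len(N),
                 n = n, k = k),
            class = "windowed_samples")
}

#' @export
print.windowed_samples <- function(x, ...) {
  cat(sprintf("<windowed_samples> %d windows (n = %d, k = %d)\n",
              dim(x$inputs)[3], x$n, x$k))
  invisible(x)
}
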