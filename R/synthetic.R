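## Synthetic bilateral gait generator: phase-locked hip/knee angle
## waveforms, alternating-stance three-axis plantar forces with the classic
## double-bump vertical profile, and marker trajectories produced by forward
## kinematics of the two-link chain so the inverse-kinematics step inverts
## them exactly. Waveform shapes are stylised, not physiological claims.

## Unit-amplitude hip flexion-extension shape: three harmonics of the gait
## phase, normalised so max |hip| = 1.
hip_shape <- function(phi) {
  raw <- sin(phi) + 0.25 * sin(2 * phi + 0.8) + 0.08 * sin(3 * phi + 1.5)
  raw / hip_shape_max()
}
hip_shape_max <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      g <- seq(0, 2 * pi, length.out = 4096)
      val <<- max(abs(sin(g) + 0.25 * sin(2 * g + 0.8) +
                        0.08 * sin(3 * g + 1.5)))
    }
    val
  }
})

## Rectified two-harmonic knee flexion curve peaking (at 1) in swing.
knee_shape <- function(phi) {
  raw <- pmax(0, 0.75 * sin(phi - 2 * pi * 0.52) +
                0.45 * sin(2 * (phi - 2 * pi * 0.52)))
  raw / knee_shape_max()
}
knee_shape_max <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      g <- seq(0, 2 * pi, length.out = 4096)
      val <<- max(pmax(0, 0.75 * sin(g - 2 * pi * 0.52) +
                         0.45 * sin(2 * (g - 2 * pi * 0.52))))
    }
    val
  }
})

## Double-bump vertical load profile over stance progress s in [0, 1],
## in body-weight units (peaks ~1.15, mid-stance valley ~0.78).
stance_fz_profile <- function(s) 1.2 * (sin(pi * s) + 0.35 * sin(3 * pi * s))

#' Subject specification for the gait simulator
#'
#' Draws (or accepts) the per-subject parameters the simulator varies
#' between subjects: gait cycle period, body weight, hip amplitude, knee
#' peak flexion, segment lengths, phase jitter and force sensor noise.
#'
#' @param subject_id identifier stored with every window cut from this
#'   subject.
#' @param period gait cycle period in seconds (drawn uniform 0.9-1.3 when
#'   `NULL`).
#' @param weight body weight in Newtons (uniform 500-900).
#' @param a_hip hip flexion-extension amplitude in radians (uniform
#'   0.25-0.45).
#' @param a_knee knee peak flexion in radians (uniform 0.9-1.2).
#' @param thigh,shank segment lengths in metres (uniform 0.38-0.46 and
#'   0.36-0.44).
#' @param stance_frac stance fraction of the gait cycle, in (0, 1)
#'   (default 0.6).
#' @param phase_jitter_sd innovation s.d. (radians) of the AR(1) phase
#'   perturbation that creates cycle-length drift; 0 disables it.
#' @param noise_sd Gaussian sensor noise s.d. added to every force channel,
#'   in Newtons.
#' @return A list of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, period = NULL, weight = NULL,
                         a_hip = NULL, a_knee = NULL,
                         thigh = NULL, shank = NULL,
                         stance_frac = 0.6,
                         phase_jitter_sd = 0.01, noise_sd = 5) {
  if (stance_frac <= 0 || stance_frac >= 1) {
    stop("stance_frac must lie strictly inside (0, 1)")
  }
  spec <- list(
    subject_id = subject_id,
    period = period %||% stats::runif(1, 0.9, 1.3),
    weight = weight %||% stats::runif(1, 500, 900),
    a_hip = a_hip %||% stats::runif(1, 0.25, 0.45),
    a_knee = a_knee %||% stats::runif(1, 0.9, 1.2),
    thigh = thigh %||% stats::runif(1, 0.38, 0.46),
    shank = shank %||% stats::runif(1, 0.36, 0.44),
    stance_frac = stance_frac,
    phase_jitter_sd = phase_jitter_sd,
    noise_sd = noise_sd)
  structure(spec, class = "subject_spec")
}

force_leg <- function(phase, spec) {
  frac <- (phase / (2 * pi)) %% 1
  stance <- frac < spec$stance_frac
  s <- frac / spec$stance_frac
  fz <- ifelse(stance, spec$weight * stance_fz_profile(s), 0)
  fy <- ifelse(stance, -0.2 * spec$weight * sin(2 * pi * s), 0)
  fx <- ifelse(stance, 0.05 * spec$weight * sin(2 * pi * s), 0)
  cbind(fx, fy, fz)
}

#' Simulate one subject's gait recording
#'
#' Generates a shared gait phase `phi(t) = 2 pi t / period` (plus an AR(1)
#' jitter), drives phase-locked hip/knee angle waveforms from it, places the
#' left and right legs exactly half a cycle apart, synthesises the
#' three-axis plantar forces (double-bump vertical profile during the
#' stance fraction, braking-then-propulsion anterior shear, small lateral
#' component, zero in swing) and adds Gaussian sensor noise to the forces.
#' Marker coordinates are produced by forward kinematics of the two-link
#' chain, so [joint_angles_from_markers()] recovers the generating angles
#' exactly.
#'
#' @param spec a [subject_spec()].
#' @param duration recording length in seconds (at least 3 gait cycles).
#' @param sampling_rate sampling rate in Hz (default 100).
#' @param seed integer seed for the jitter and noise draws.
#' @return A list with `markers`, `forces`, `angles` (the three series
#'   types) and `spec`.
#' @export
simulate_subject <- function(spec, duration = 60, sampling_rate = 100,
                             seed = 1L) {
  stopifnot(inherits(spec, "subject_spec"))
  if (duration < 3 * spec$period) {
    stop("duration must cover at least 3 gait cycles")
  }
  set.seed(seed)
  nsamp <- as.integer(round(duration * sampling_rate))
  t <- (seq_len(nsamp) - 1L) / sampling_rate

  jitter <- numeric(nsamp)
  if (spec$phase_jitter_sd > 0) {
    e <- stats::rnorm(nsamp, sd = spec$phase_jitter_sd)
    jitter <- as.numeric(stats::filter(e, 0.95, method = "recursive"))
  }
  phi_l <- 2 * pi * t / spec$period + jitter
  phi_r <- phi_l + pi                       # exactly half a cycle apart

  q1 <- spec$a_hip * hip_shape(phi_l)
  q2 <- spec$a_knee * knee_shape(phi_l)
  q3 <- spec$a_hip * hip_shape(phi_r)
  q4 <- spec$a_knee * knee_shape(phi_r)
  angles <- angle_series(t, cbind(q1, q2, q3, q4))

  fl <- force_leg(phi_l, spec)
  fr <- force_leg(phi_r, spec)
  fmat <- cbind(fl, fr)
  if (spec$noise_sd > 0) {
    fmat <- fmat + matrix(stats::rnorm(length(fmat), sd = spec$noise_sd),
                          nrow(fmat))
  }
  forces <- force_series(t, fmat)

  hip_x <- 0.02 * sin(2 * phi_l)
  hip_z <- 0.92 + 0.015 * sin(2 * phi_l)
  left <- two_link_forward(q1, q2, hip_x, hip_z, spec$thigh, spec$shank)
  right <- two_link_forward(q3, q4, hip_x, hip_z, spec$thigh, spec$shank)
  markers <- marker_series(t, cbind(left, right))

  list(markers = markers, forces = forces, angles = angles, spec = spec)
}

#' Simulate a cohort of subjects in memory
#'
#' Draws one [subject_spec()] per subject reproducibly from `master_seed`
#' and simulates each with its own derived seed.
#'
#' @param n_subjects number of subjects (the reference cohort has 35; at
#'   least 4 so a subject-level test split remains possible).
#' @param duration,sampling_rate passed to [simulate_subject()].
#' @param master_seed integer master seed.
#' @param ... further arguments passed to [subject_spec()] (e.g.
#'   `noise_sd`).
#' @return A list of per-subject simulation results.
#' @export
simulate_cohort <- function(n_subjects = 35L, duration = 60,
                            sampling_rate = 100, master_seed = 1L, ...) {
  if (n_subjects < 4L) stop("need at least 4 subjects (3 test + rest)")
  set.seed(derive_seed(master_seed, "subject_specs"))
  specs <- lapply(seq_len(n_subjects), function(i) {
    subject_spec(subject_id = sprintf("S%02d", i), ...)
  })
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(specs[[i]], duration, sampling_rate,
                     seed = derive_seed(master_seed, paste0("subject_", i)))
  })
}

fmt_num <- function(x) sprintf("%.6f", x)

write_series_csv <- function(series, path) {
  df <- data.frame(time = fmt_num(series$time))
  for (j in seq_len(ncol(series$data))) {
    df[[colnames(series$data)[j]]] <- fmt_num(series$data[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Generate and write a synthetic gait cohort to disk
#'
#' Writes one marker CSV and one force CSV per subject (schemas matching the
#' preprocessing readers) plus a JSON manifest of the drawn subject
#' parameters. Identical `master_seed` gives byte-identical files.
#'
#' @inheritParams simulate_cohort
#' @param out_dir output directory (created if needed).
#' @param overwrite set `TRUE` to allow writing into a directory that
#'   already contains a manifest.
#' @param ... passed to [subject_spec()].
#' @return Invisibly, the manifest list.
#' @export
generate_dataset <- function(n_subjects = 35L, duration = 60,
                             sampling_rate = 100, master_seed = 1L,
                             out_dir, overwrite = FALSE, ...) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("output already contains a cohort manifest; use overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(n_subjects, duration, sampling_rate,
                            master_seed, ...)
  entries <- lapply(cohort, function(sub) {
    id <- sub$spec$subject_id
    mfile <- file.path(out_dir, paste0("markers_", id, ".csv"))
    ffile <- file.path(out_dir, paste0("forces_", id, ".csv"))
    write_series_csv(sub$markers, mfile)
    write_series_csv(sub$forces, ffile)
    c(sub$spec[c("subject_id", "period", "weight", "a_hip", "a_knee",
                 "thigh", "shank", "stance_frac", "phase_jitter_sd",
                 "noise_sd")],
      list(markers = basename(mfile), forces = basename(ffile)))
  })
  manifest <- list(n_subjects = n_subjects, duration = duration,
                   sampling_rate = sampling_rate, master_seed = master_seed,
                   subjects = entries)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [generate_dataset()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return A list of per-subject lists with `markers`, `forces` and the
#'   manifest entry as `spec_info`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subs <- manifest$subjects
  lapply(seq_len(nrow(subs)), function(i) {
    m <- utils::read.csv(file.path(dir, subs$markers[i]))
    f <- utils::read.csv(file.path(dir, subs$forces[i]))
    list(markers = marker_series(m$time, as.matrix(m[, marker_cols])),
         forces = force_series(f$time, as.matrix(f[, force_cols])),
         spec_info = subs[i, ])
  })
}

#' Inject short missing runs into a series (preprocessing exercise)
#'
#' Randomly masks runs of 1-8 samples so the gap-filling and rejection
#' paths can be exercised on synthetic data.
#'
#' @param series a `channel_series`.
#' @param n_gaps number of runs to mask.
#' @param max_len longest run length (default 8).
#' @param seed integer seed.
#' @return The series with masked (NA) runs.
#' @export
inject_gaps <- function(series, n_gaps = 5L, max_len = 8L, seed = 1L) {
  set.seed(seed)
  n <- nrow(series$data)
  for (i in seq_len(n_gaps)) {
    len <- sample.int(max_len, 1L)
    j <- sample.int(ncol(series$data), 1L)
    s <- sample.int(n - len - 2L, 1L) + 1L
    series$data[s:(s + len - 1L), j] <- NA_real_
  }
  series$mask <- !is.finite(series$data)
  series
}
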