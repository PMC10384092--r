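#' Variational mode decomposition configuration
#'
#' @param K number of intrinsic modes (3 for plantar-force channels).
#' @param alpha bandwidth penalty weight of the quadratic term; larger values
#'   give narrower-band modes.
#' @param tau dual-ascent step for the Lagrange multiplier; 0 gives the
#'   noise-tolerant variant in which the exact-reconstruction constraint is
#'   enforced only through the penalty.
#' @param tol convergence tolerance on the summed relative change of the
#'   mode spectra between iterations.
#' @param max_iter iteration cap for the alternating-direction updates.
#' @param mirror if `TRUE` the signal is even-mirror-extended to twice its
#'   length before the FFT and the centre half retained afterwards, which
#'   suppresses edge ringing on short windows.
#' @return A list of class `vmd_config`.
#' @export
vmd_config <- function(K = 3L, alpha = 2000, tau = 0, tol = 1e-7,
                       max_iter = 500L, mirror = TRUE) {
  stopifnot(K >= 1L, alpha > 0, tau >= 0, tol > 0, max_iter >= 1L)
  structure(list(K = as.integer(K), alpha = alpha, tau = tau, tol = tol,
                 max_iter = as.integer(max_iter), mirror = mirror),
            class = "vmd_config")
}

#' Variational mode decomposition of a real signal
#'
#' Decomposes `signal` into `K` band-limited intrinsic modes by the
#' frequency-domain alternating-direction scheme: each mode spectrum is
#' updated by a Wiener-like filter centred on its current frequency, each
#' centre frequency by the power-weighted centroid of the mode's positive
#' half-spectrum, and the Lagrange multiplier by dual ascent scaled by
#' `tau`, iterating until the summed relative change of the mode spectra
#' falls below `tol`.
#'
#' Centre frequencies are initialised uniformly on (0, 0.5) cycles/sample
#' (seed-free), and the returned modes are sorted by ascending centre
#' frequency.
#'
#' @param signal real numeric vector, length at least 16.
#' @param config a [vmd_config()].
#' @return A list of class `vmd_result`: `modes` (`K x length(signal)`),
#'   `omegas` (ascending, cycles/sample), `iterations`, `residual`
#'   (relative l2 reconstruction error) and `converged`.
#' @export
vmd_decompose <- function(signal, config = vmd_config()) {
  if (!is.numeric(signal) || length(signal) < 16L) {
    stop("signal must be numeric with length >= 16")
  }
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  K <- config$K
  L <- length(signal)

  if (config$mirror) {
    hl <- L %/% 2L
    hr <- if ((L + 2L * hl) %% 2L == 0L) hl else hl + 1L
    x <- c(rev(signal[seq_len(hl)]), signal,
           rev(signal[(L - hr + 1L):L]))
    first <- hl + 1L
  } else {
    x <- if (L %% 2L == 0L) signal else c(signal, signal[L])
    first <- 1L
  }
  Te <- length(x)
  half <- Te %/% 2L

  ## centred frequency grid; positive half is indices (half+1):Te
  freqs <- (seq_len(Te) - 1) / Te - 0.5
  fftshift <- function(v) v[c((half + 1L):Te, seq_len(half))]
  ifftshift <- function(v) v[c((Te - half + 1L):Te, seq_len(Te - half))]

  f_hat <- fftshift(stats::fft(x))
  f_plus <- f_hat
  f_plus[seq_len(half)] <- 0

  u_hat <- matrix(0 + 0i, Te, K)
  omega <- 0.5 * seq_len(K) / (K + 1)   # uniform on (0, 0.5)
  lambda_hat <- complex(Te)
  pos <- (half + 1L):Te
  wpos <- freqs[pos]
  denom_base <- 2 * config$alpha

  n <- 0L
  udiff <- Inf
  while (n < config$max_iter && udiff > config$tol) {
    n <- n + 1L
    u_prev <- u_hat
    sum_u <- rowSums(u_hat)
    for (k in seq_len(K)) {
      sum_u <- sum_u - u_hat[, k]
      num <- f_plus - sum_u + lambda_hat / 2
      u_hat[, k] <- num / (1 + denom_base * (freqs - omega[k])^2)
      u_hat[seq_len(half), k] <- 0
      p <- Mod(u_hat[pos, k])^2
      sp <- sum(p)
      if (sp > 0) omega[k] <- sum(wpos * p) / sp
      sum_u <- sum_u + u_hat[, k]
    }
    if (config$tau > 0) {
      lambda_hat <- lambda_hat + config$tau * (f_plus - rowSums(u_hat))
    }
    if (anyNA(u_hat)) {
      stop("numerical failure (NaN) in VMD at iteration ", n)
    }
    num0 <- colSums(Mod(u_hat - u_prev)^2)
    den0 <- colSums(Mod(u_prev)^2)
    udiff <- sum(ifelse(den0 > 0, num0 / den0, num0))
  }

  ## back to time domain: hermitian-symmetrise the one-sided spectra
  modes <- matrix(0, K, L)
  for (k in seq_len(K)) {
    spec <- u_hat[, k]
    full <- spec
    ## mirror the one-sided spectrum about the centre bin (half+1);
    ## the leftmost bin takes the conjugate of the last, as there is no
    ## exact positive partner for the -Nyquist bin
    ii <- seq_len(half)
    full[ii] <- Conj(spec[pmin(2L * half + 2L - ii, Te)])
    ut <- Re(stats::fft(ifftshift(full), inverse = TRUE)) / Te
    modes[k, ] <- ut[first:(first + L - 1L)]
  }
  ord <- order(omega)
  modes <- modes[ord, , drop = FALSE]
  omega <- omega[ord]

  recon <- colSums(modes)
  snorm <- sqrt(sum(signal^2))
  residual <- if (snorm > 0) sqrt(sum((signal - recon)^2)) / snorm else 0
  converged <- udiff <= config$tol
  if (!converged) {
    warning("VMD did not converge within ", config$max_iter, " iterations")
  }
  structure(list(modes = modes, omegas = omega, iterations = n,
                 residual = residual, converged = converged),
            class = "vmd_result")
}

#' @export
print.vmd_result <- function(x, ...) {
  cat(sprintf("VMD result: %d modes over %d samples\n",
              nrow(x$modes), ncol(x$modes)))
  cat("  centre frequencies (cycles/sample):",
      paste(signif(x$omegas, 4), collapse = ", "), "\n")
  cat(sprintf("  iterations %d, relative residual %.3g%s\n",
              x$iterations, x$residual,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Per-channel VMD of a force window
#'
#' Applies [vmd_decompose()] to each of the six force channels of an `n x 6`
#' window and concatenates the resulting modes along the feature axis,
#' channel-major with modes in ascending centre frequency within each
#' channel, giving the `n x (K*6)` block the decoder consumes (`n x 18` for
#' `K = 3`).
#'
#' @param window numeric `n x 6` matrix (one moving-window force block).
#' @param config a [vmd_config()].
#' @return An `n x (K * ncol(window))` matrix.
#' @export
decompose_window <- function(window, config = vmd_config()) {
  window <- as.matrix(window)
  n <- nrow(window); nc <- ncol(window)
  out <- matrix(0, n, config$K * nc)
  for (j in seq_len(nc)) {
    r <- tryCatch(
      suppressWarnings(vmd_decompose(window[, j], config)),
      error = function(e) {
        stop("VMD failed on channel ", j, ": ", conditionMessage(e),
             call. = FALSE)
      })
    out[, (j - 1L) * config$K + seq_len(config$K)] <- t(r$modes)
  }
  out
}

#' Session-scope VMD of a multichannel force series
#'
#' Decomposes each column of a full recording once, rather than per moving
#' window; the mode series can then be windowed exactly like the forces.
#' This is the cheap path when many overlapping windows are cut from one
#' recording.
#'
#' @param mat numeric `L x C` matrix of force channels.
#' @param config a [vmd_config()].
#' @return An `L x (K * C)` matrix, channel-major, modes ordered by
#'   ascending centre frequency within each channel.
#' @export
vmd_series <- function(mat, config = vmd_config()) {
  decompose_window(mat, config)
}
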