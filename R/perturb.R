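# Sinusoidal state perturbation of the closed loop and Wigner-Ville
# time-frequency energy analysis of the response.
#
# The perturbed controller computes its feedback on the corrupted state
# x_n(t) = x(t) + kappa * cos(gamma t) * 1 (the same scalar added to every
# state component), modelling an oscillatory disturbance in the neural
# feedback path. The response is summarized by the cumulative time-frequency
# energy of a trajectory signal (by default the vertical wrist velocity)
# computed from a discrete pseudo Wigner-Ville distribution.

#' Simulate the closed loop under sinusoidal state perturbation
#'
#' Integrates the plant with feedback computed on the perturbed state
#' `x + kappa * cos(2 pi f t) * 1`, i.e.
#' `c(t) = c* - K (x + kappa cos(gamma t) 1 - x*)`.
#'
#' @param system an `"arm_dynamics"` or `"arm_linsys"` object.
#' @param gain `"lqr_gain"` or 3 x 6 matrix; the unperturbed closed loop must
#'   be stable.
#' @param kappa perturbation amplitude (default 0.2, dimensionless in the
#'   state units).
#' @param freq_hz perturbation frequency in Hz (angular frequency
#'   `gamma = 2 pi freq_hz` rad/s).
#' @param x0 initial state; default: the target posture (pure perturbation
#'   response).
#' @param x_star target equilibrium; defaults to the linearization point.
#' @param t_final duration (s), default 60 s.
#' @param dt output sampling interval (s), default 1/60.
#' @param ... tolerances passed to [simulate_arm()].
#' @return an `"arm_trajectory"`.
#' @export
simulate_perturbed <- function(system, gain, kappa = 0.2, freq_hz = 1,
                               x0 = NULL, x_star = NULL, t_final = 60,
                               dt = 1 / 60, ...) {
  K <- if (inherits(gain, "lqr_gain")) gain$K else as.matrix(gain)
  if (kappa < 0 || freq_hz < 0)
    stop("'kappa' and 'freq_hz' must be nonnegative", call. = FALSE)
  if (is.null(x_star)) {
    x_star <- if (inherits(system, "arm_linsys")) system$x_star
    else if (inherits(gain, "lqr_gain") && inherits(gain$system, "arm_linsys"))
      gain$system$x_star
    else stop("'x_star' is required", call. = FALSE)
  }
  x_star <- as.numeric(x_star)
  if (length(x_star) == 3L) x_star <- c(x_star, 0, 0, 0)
  if (is.null(x0)) x0 <- x_star
  c_star <- if (inherits(system, "arm_linsys")) system$c_star
  else gravity_torque(system, x_star[1:3])
  gamma <- 2 * pi * freq_hz
  ctrl <- function(t, x) {
    xn <- x + kappa * cos(gamma * t)
    drop(c_star - K %*% (xn - x_star))
  }
  simulate_arm(system, ctrl, x0 = x0, t_final = t_final, dt = dt, ...)
}

#' Discrete pseudo Wigner-Ville distribution
#'
#' Time-frequency energy density `W(t, f)` of a uniformly sampled real
#' signal, computed as the windowed (frequency-smoothed) Wigner-Ville
#' distribution of the signal's analytic extension:
#' `W[n, k] = dt * sum_m h[m] z[n+m] Conj(z[n-m]) exp(-2i pi k m / Nf)`,
#' where `z` is the analytic signal and `h` an odd-length Hann lag window.
#' Using the analytic signal and the lag window suppresses the cross-terms of
#' the raw transform (available with `analytic = FALSE, window = NULL`). The
#' distribution is scaled so that its double integral over the time-frequency
#' plane equals the signal energy `sum(x^2) / fs` for zero-mean signals.
#'
#' @param x real signal, length >= 64.
#' @param fs sample rate (Hz).
#' @param window odd lag-window length in samples (default 127), or `NULL`
#'   for the full unwindowed kernel.
#' @param nfreq number of frequency bins (default: next power of two >= the
#'   window length, at least 256); the frequency grid spans 0 .. fs/2.
#' @param analytic compute the WVD of the analytic signal (default) rather
#'   than of the raw real signal.
#' @return an object of class `"tf_map"`: list with `time` (s), `freq` (Hz),
#'   `W` (time x frequency matrix, real), `fs`.
#' @export
wvd <- function(x, fs, window = 127L, nfreq = NULL, analytic = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 64L) stop("signal must have at least 64 samples", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be positive", call. = FALSE)
  z <- if (analytic) .analytic_signal(x) else as.complex(x)
  if (is.null(window)) {
    Lh <- (n - 1L) %/% 2L
    h <- rep(1, 2L * Lh + 1L)
  } else {
    window <- as.integer(window)
    if (window %% 2L == 0L) stop("'window' must be odd", call. = FALSE)
    Lh <- (window - 1L) %/% 2L
    # Hann lag window, unit at zero lag so the time marginal is preserved
    h <- 0.5 * (1 + cos(pi * seq(-Lh, Lh) / (Lh + 1L)))
  }
  if (is.null(nfreq)) nfreq <- max(256L, 2L^ceiling(log2(2L * Lh + 1L)))
  if (nfreq < 2L * Lh + 1L) stop("'nfreq' must cover the lag window", call. = FALSE)
  # kernel matrix: rows lag index m = 0..Lh then (wrapped) -Lh..-1
  Kmat <- matrix(0 + 0i, nfreq, n)
  for (m in 0:Lh) {
    idx_t <- seq_len(n)
    valid <- idx_t + m <= n & idx_t - m >= 1L
    r <- complex(length.out = n)
    r[valid] <- z[idx_t[valid] + m] * Conj(z[idx_t[valid] - m])
    w <- h[Lh + 1L + m]
    Kmat[m + 1L, ] <- w * r
    if (m > 0L) Kmat[nfreq - m + 1L, ] <- w * Conj(r)
  }
  W <- Re(stats::mvfft(Kmat))          # nfreq x n, real up to rounding
  # scale: sum(W) * dt * df = sum(|z|^2) / 2 * dt  (= signal energy for
  # zero-mean x), with df = fs / (2 nfreq), dt = 1/fs; in raw (real-signal)
  # mode the grid still covers positive frequencies only while the
  # distribution is symmetric, hence the factor 2
  W <- t(W) / fs
  if (!analytic) W <- 2 * W
  structure(list(time = (seq_len(n) - 1L) / fs,
                 freq = (seq_len(nfreq) - 1L) * fs / (2 * nfreq),
                 W = W, fs = fs),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("Time-frequency map: %d samples x %d bins, t <= %.3g s, f <= %.4g Hz\n",
              nrow(x$W), ncol(x$W), max(x$time), max(x$freq)))
  invisible(x)
}

#' Cumulative time-frequency energy
#'
#' The double integral of the distribution over `[0, t_max] x [0, f_max]` by
#' the trapezoid rule. Negative residue of the smoothed distribution is
#' clipped at zero by default so the cumulative surface is nondecreasing in
#' both limits.
#'
#' @param map a `"tf_map"` from [wvd()].
#' @param t_max,f_max upper limits (s, Hz); default: the full grid. Must lie
#'   within the grid.
#' @param clip clip negative values of W at zero before integrating.
#' @return scalar energy.
#' @export
cumulative_energy <- function(map, t_max = NULL, f_max = NULL, clip = TRUE) {
  stopifnot(inherits(map, "tf_map"))
  if (is.null(t_max)) t_max <- max(map$time)
  if (is.null(f_max)) f_max <- max(map$freq)
  if (t_max < 0 || t_max > max(map$time) + 1e-9 ||
      f_max < 0 || f_max > max(map$freq) + 1e-9)
    stop("integration limits outside the time-frequency grid", call. = FALSE)
  it <- map$time <= t_max + 1e-12
  jf <- map$freq <= f_max + 1e-12
  if (sum(it) < 2L || sum(jf) < 2L) return(0)
  W <- map$W[it, jf, drop = FALSE]
  if (clip) W[W < 0] <- 0
  # iterated trapezoid
  row_int <- apply(W, 1, function(r) .trapz(map$freq[jf], r))
  .trapz(map$time[it], row_int)
}

#' Frequency sweep of the perturbation response
#'
#' For each perturbation frequency: simulate the perturbed closed loop,
#' extract the selected response signal, compute its pseudo Wigner-Ville
#' distribution and its cumulative energy over the configured
#' time-frequency window, then normalize the curve by its maximum.
#'
#' @param system `"arm_dynamics"` or `"arm_linsys"`.
#' @param gain `"lqr_gain"` or 3 x 6 matrix.
#' @param freqs_hz perturbation frequencies (Hz); default 0.5 to 45.5 in 1 Hz
#'   steps.
#' @param kappa perturbation amplitude.
#' @param signal response signal: `"wrist_vy"` (vertical wrist velocity,
#'   default) or `"omega1"`, `"omega2"`, `"omega3"`.
#' @param x0,x_star,t_final,dt as in [simulate_perturbed()].
#' @param t_max,f_max cumulative-energy window; defaults: full duration and
#'   the Nyquist frequency of the sampled output. (Perturbation frequencies
#'   above Nyquist refer to the input oscillation; their sampled response is
#'   evaluated on the resolvable band.)
#' @param window,nfreq passed to [wvd()].
#' @param ... tolerances passed to the integrator.
#' @return a data frame of class `"arm_freqsweep"` with columns `freq_hz`,
#'   `energy`, `energy_normalized`.
#' @export
frequency_sweep <- function(system, gain, freqs_hz = seq(0.5, 45.5, by = 1),
                            kappa = 0.2, signal = c("wrist_vy", "omega1",
                                                    "omega2", "omega3"),
                            x0 = NULL, x_star = NULL, t_final = 60, dt = 1 / 60,
                            t_max = NULL, f_max = NULL,
                            window = 127L, nfreq = NULL, ...) {
  if (!length(freqs_hz)) stop("'freqs_hz' must be non-empty", call. = FALSE)
  signal <- match.arg(signal)
  energy <- vapply(freqs_hz, function(f) {
    traj <- simulate_perturbed(system, gain, kappa = kappa, freq_hz = f,
                               x0 = x0, x_star = x_star,
                               t_final = t_final, dt = dt, ...)
    sig <- switch(signal,
                  wrist_vy = traj$wrist_velocity[, "y"],
                  omega1 = traj$state[, "omega1"],
                  omega2 = traj$state[, "omega2"],
                  omega3 = traj$state[, "omega3"])
    map <- wvd(sig, fs = 1 / dt, window = window, nfreq = nfreq)
    cumulative_energy(map, t_max = t_max, f_max = f_max)
  }, numeric(1))
  out <- data.frame(freq_hz = freqs_hz, energy = energy,
                    energy_normalized = energy / max(energy))
  class(out) <- c("arm_freqsweep", "data.frame")
  out
}

#' @export
plot.arm_freqsweep <- function(x, ...) {
  graphics::plot(x$freq_hz, x$energy_normalized, type = "b", pch = 16,
                 xlab = "perturbation frequency (Hz)",
                 ylab = "normalized cumulative energy",
                 main = "Perturbation frequency response", ...)
  invisible(x)
}
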