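# Inverse optimal control: estimate the cost-functional penalties
# (theta_p, omega_p) from a measured wrist-height trajectory.
#
# The estimator searches in the reparameterization
#   rho   = log10(theta_p / omega_p)   (log ratio)
#   sigma = (log10 theta_p + log10 omega_p) / 2   (log scale)
# because the two coordinates have vastly different identifiability: the
# closed-loop movement shape is governed almost entirely by the ratio (the
# slow closed-loop modes decay at ~sqrt(theta_p/omega_p)), while the common
# scale enters the wrist trajectory only through O(1e-3) relative corrections
# (the gravity term of A against the feedback, and the fast-manifold onset
# transient). Stage 1 fits rho alone at a fixed reference scale by golden
# section; stage 2 refines (rho, sigma) jointly by deterministic coordinate
# descent with a Nelder-Mead polish, and the data-driven scale is accepted
# only when the joint fit improves the stage-1 error by more than `scale_tol`
# (relative) — otherwise the scale is reported at the reference value with
# `scale_identified = FALSE`.
# On clean recordings the improvement from the true scale is large and the
# scale is recovered; at realistic marker-noise levels the scale direction of
# the error landscape is noise-dominated and the guard prevents reporting a
# spurious value.

# zero-phase low-pass with odd-reflection padding to suppress end transients;
# .make_lowpass precomputes the filter for repeated application
.make_lowpass <- function(fs, cutoff) {
  if (is.null(cutoff) || !is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    return(identity)
  bf <- signal::butter(2, cutoff / (fs / 2))
  pad0 <- max(12L, round(3 * fs / cutoff))
  function(x) {
    n <- length(x)
    pad <- min(n - 1L, pad0)
    xa <- 2 * x[1] - x[(pad + 1L):2L]
    xb <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- as.numeric(signal::filtfilt(bf, c(xa, x, xb)))
    y[(pad + 1L):(pad + n)]
  }
}

.lowpass <- function(x, fs, cutoff) .make_lowpass(fs, cutoff)(x)

#' l2 trajectory error between simulated and measured wrist heights
#'
#' The scalar fitting criterion: the l2 norm
#' `sqrt(sum((y_sim - y_meas)^2))` of the difference between the vertical
#' wrist coordinates, sample by sample on a shared uniform grid.
#'
#' @param sim,measured either two `"arm_trajectory"` objects (compared over
#'   their overlapping time window, which must share the sampling interval
#'   and phase) or two bare numeric series of equal length.
#' @return non-negative scalar.
#' @export
trajectory_error <- function(sim, measured) {
  if (inherits(sim, "arm_trajectory") && inherits(measured, "arm_trajectory")) {
    dt1 <- .uniform_dt(sim$time); dt2 <- .uniform_dt(measured$time)
    if (abs(dt1 - dt2) > 1e-9 * dt1)
      stop("trajectories are on different grids; resample to a common rate first",
           call. = FALSE)
    t0 <- max(sim$time[1], measured$time[1])
    t1 <- min(sim$time[length(sim$time)], measured$time[length(measured$time)])
    if (t1 <= t0) stop("trajectories do not overlap in time", call. = FALSE)
    off <- (measured$time[1] - sim$time[1]) / dt1
    if (abs(off - round(off)) > 1e-6)
      stop("trajectory grids are offset by a fraction of a sample; resample first",
           call. = FALSE)
    i1 <- which(sim$time >= t0 - dt1 / 2 & sim$time <= t1 + dt1 / 2)
    i2 <- which(measured$time >= t0 - dt1 / 2 & measured$time <= t1 + dt1 / 2)
    y1 <- sim$wrist[i1, "y"]; y2 <- measured$wrist[i2, "y"]
  } else {
    y1 <- as.numeric(sim); y2 <- as.numeric(measured)
    if (length(y1) != length(y2))
      stop("series have different lengths; resample to a common grid first",
           call. = FALSE)
  }
  sqrt(sum((y1 - y2)^2))
}

# wrist height (relative to shoulder) from deviation-state rows + target
.wrist_y_from_xi <- function(xi, x_star, lengths) {
  th <- sweep(xi[, 1:3, drop = FALSE], 2, x_star[1:3], "+")
  phi1 <- th[, 1]; phi2 <- th[, 1] + th[, 2]
  -(lengths[1] * cos(phi1) + lengths[2] * cos(phi2))
}

#' Fit LQR cost weights to a recorded arm flexion
#'
#' The package's central model fit: finds the penalty pair
#' `(theta_p, omega_p)` whose optimal LQR controller, driving the subject's
#' scaled arm model from the measured initial posture to the measured final
#' posture, reproduces the measured vertical wrist trajectory with minimal
#' l2 error.
#'
#' The arm model is scaled with the segment lengths measured from the static
#' window; masses and inertias follow the anthropometric defaults of
#' [arm_geometry()] for the given body mass. Candidate controllers are
#' evaluated on the plant linearized at the target posture (exact sampled
#' propagation); the reported trajectory is re-simulated on the nonlinear
#' plant. Both the measured and each candidate wrist series are passed
#' through the same zero-phase low-pass filter (`control$cutoff_hz`, default
#' 6 Hz, far above the movement bandwidth) so that marker noise does not
#' dominate the criterion.
#'
#' @param input an `"arm_input"` from [prepare_input()] /
#'   [extract_planar_angles()], or a raw [skeleton_recording()] (then
#'   [prepare_input()] is applied with `static_window`).
#' @param body_mass subject body mass (kg) for the anthropometric scaling.
#' @param limits [joint_limits()] used for the nonlinear re-simulation.
#' @param static_window static rest window length (s) when `input` is a raw
#'   recording.
#' @param x_star target posture; default: the smoothed final posture of the
#'   recording (zero velocity).
#' @param x0 initial state; default: the smoothed posture at movement onset
#'   (end of the static window), zero velocity.
#' @param control list of optimizer settings, see `Details`.
#' @details `control` entries (with defaults): `sigma_ref = 6` (log10
#'   reference scale anchoring the weakly identified overall weight level),
#'   `scale_tol = 0.05` (minimum relative error improvement required to
#'   accept a data-driven scale; clean recordings improve by ~97% when the
#'   scale moves to its true value, noise-dominated ones by under ~2%), `bounds = c(3, 9)` (log10 box for each
#'   weight), `rho_interval = c(-3, 3)` (log10 ratio search interval),
#'   `reltol = 1e-12`, `maxit = 400`, `rounds = 6` (stage-2 coordinate
#'   descent rounds), `restarts = 3` (final Nelder-Mead polish cycles from
#'   the incumbent; the whole search is deterministic), `cutoff_hz = 6`
#'   (low-pass cutoff of the zero-phase filter applied identically to the
#'   measured and candidate series; `NULL` disables).
#' @return an object of class `"armioc"` with elements including `weights`
#'   (the fitted [cost_weights()]), `error` (criterion at the optimum),
#'   `converged`, `scale_identified`, `trace` (matrix of probed weights and
#'   errors for the reported branch), `scale_probe` (the rejected or accepted
#'   joint refinement), `gain`, `linsys`, `x0`, `x_star`, `geometry`,
#'   `trajectory` (nonlinear re-simulation at the optimum) and the measured
#'   series used.
#' @seealso [preset_weights()], [stiffness()], [synthetic_recording()]
#' @export
armioc <- function(input, body_mass = 75, limits = joint_limits(),
                   static_window = 5, x_star = NULL, x0 = NULL,
                   control = list()) {
  if (inherits(input, "skeleton_recording"))
    input <- prepare_input(input, static_window = static_window)
  stopifnot(inherits(input, "arm_input"))
  ctl <- utils::modifyList(
    list(sigma_ref = 6, scale_tol = 0.05, bounds = c(3, 9),
         rho_interval = c(-3, 3), reltol = 1e-12, maxit = 400, restarts = 3,
         rounds = 6, cutoff_hz = 6),
    control)
  fs <- input$fps
  sw <- if (!is.null(input$static_window)) input$static_window else 0
  onset <- which(input$time >= input$time[1] + sw)[1]
  if (is.na(onset) || onset >= length(input$time) - 10L)
    stop("no movement window after the static window", call. = FALSE)
  n <- length(input$time)
  # Endpoint postures from window means of the raw extracted angles (no
  # non-causal smoothing, which would bleed the movement into the static
  # window). x0: a pre-onset window with a 0.5 s margin from the onset so
  # interpolation ripple around the movement kink does not leak in. x*: the
  # movement settles exponentially, so the plain tail mean lags the asymptote
  # by the unsettled residue; three trailing window means are extrapolated by
  # Aitken's delta-squared (exact for an exponential approach), guarded to
  # fall back to the last window mean when the successive differences are
  # noise-dominated rather than geometric.
  if (is.null(x0)) {
    head_idx <- max(1L, onset - round(2.5 * fs)):max(1L, onset - round(0.5 * fs))
    x0 <- c(colMeans(input$theta[head_idx, , drop = FALSE]), 0, 0, 0)
  }
  if (is.null(x_star)) {
    wlen <- round(0.8 * fs); e1 <- n - 2L
    m <- vapply(0:2, function(k)
      colMeans(input$theta[(e1 - (k + 1L) * wlen + 1L):(e1 - k * wlen), , drop = FALSE]),
      numeric(3))
    xst <- m[, 1]
    for (j in 1:3) {
      d1 <- m[j, 1] - m[j, 2]; d2 <- m[j, 2] - m[j, 3]
      if (sign(d1) == sign(d2) && abs(d1) > 0.05 * abs(d2) && abs(d1) < 0.95 * abs(d2)) {
        corr <- d1^2 / (d2 - d1)
        if (abs(corr) < 0.02) xst[j] <- m[j, 1] + corr
      }
    }
    x_star <- c(xst, 0, 0, 0)
  }
  x_star <- as.numeric(x_star); x0 <- as.numeric(x0)
  if (length(x_star) == 3L) x_star <- c(x_star, 0, 0, 0)
  if (length(x0) == 3L) x0 <- c(x0, 0, 0, 0)

  geometry <- arm_geometry(lengths = input$lengths, body_mass = body_mass)
  dyn <- arm_dynamics(geometry, limits)
  linsys <- linearize(dyn, x_star)
  A <- linsys$A; B <- linsys$B
  xi0 <- x0 - x_star
  n_steps <- n - onset
  dt <- 1 / fs

  y_meas <- input$wrist_y[onset:n] - input$wrist_y[onset]
  y_meas_f <- .lowpass(y_meas, fs, ctl$cutoff_hz)

  lo <- ctl$bounds[1]; hi <- ctl$bounds[2]
  n_fail <- 0L
  lp <- .make_lowpass(fs, ctl$cutoff_hz)
  trace_env <- new.env(parent = emptyenv())
  trace_env$rows <- list()
  objective <- function(rho, sigma, record = TRUE) {
    lt <- sigma + rho / 2; lw <- sigma - rho / 2
    if (lt < lo || lt > hi || lw < lo || lw > hi) {
      pen <- sum(pmax(0, c(lo - lt, lt - hi, lo - lw, lw - hi)))
      return(1e6 * (1 + pen))
    }
    Z <- diag(rep(c(10^lt, 10^lw), each = 3))
    err <- tryCatch({
      S <- solve_care(A, B, Z, diag(3))$S
      K <- t(B) %*% S
      xi <- .propagate_linear(A - B %*% K, xi0, n_steps, dt)
      y <- .wrist_y_from_xi(xi, x_star, geometry$lengths)
      sqrt(sum((lp(y - y[1]) - y_meas_f)^2))
    }, error = function(e) NA_real_)
    if (is.na(err)) {
      n_fail <<- n_fail + 1L
      return(1e7)
    }
    if (record)
      trace_env$rows[[length(trace_env$rows) + 1L]] <- c(10^lt, 10^lw, err)
    err
  }

  # stage 1: ratio at the reference scale
  s1 <- stats::optimize(function(r) objective(r, ctl$sigma_ref),
                        interval = ctl$rho_interval, tol = 1e-10)
  rho1 <- s1$minimum; err1 <- s1$objective
  if (n_fail > 0 && length(trace_env$rows) == 0L)
    stop("all candidate controllers failed (Riccati/stability); ",
         "check the recording and the linearization posture", call. = FALSE)

  # stage 2: joint (rho, sigma) refinement. The error surface is a long
  # shallow valley along sigma with steep walls across rho, so deterministic
  # coordinate descent (golden section per coordinate) converges where a
  # joint simplex stalls; a final Nelder-Mead polish handles the residual
  # cross-coupling. Entirely derivative-free and deterministic.
  nm_converged <- TRUE
  cur <- list(par = c(rho1, ctl$sigma_ref),
              value = objective(rho1, ctl$sigma_ref, record = FALSE))
  for (round in seq_len(ctl$rounds)) {
    prev <- cur$value
    sig_int <- c(lo + abs(cur$par[1]) / 2, hi - abs(cur$par[1]) / 2)
    os <- stats::optimize(function(s) objective(cur$par[1], s, record = FALSE),
                          interval = sig_int, tol = 1e-10)
    if (os$objective < cur$value) cur <- list(par = c(cur$par[1], os$minimum),
                                              value = os$objective)
    orr <- stats::optimize(function(r) objective(r, cur$par[2], record = FALSE),
                           interval = ctl$rho_interval, tol = 1e-10)
    if (orr$objective < cur$value) cur <- list(par = c(orr$minimum, cur$par[2]),
                                               value = orr$objective)
    if (prev - cur$value <= ctl$reltol * (abs(prev) + 1e-300)) break
  }
  for (r in seq_len(ctl$restarts)) {
    o <- stats::optim(cur$par, function(p) objective(p[1], p[2], record = FALSE),
                      method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    if (o$value < cur$value) {
      cur <- list(par = o$par, value = o$value)
      # still improving on the last allowed cycle without meeting reltol
      nm_converged <- o$convergence == 0 || r < ctl$restarts
    } else {
      nm_converged <- TRUE   # restart could not improve: stationary
      break
    }
  }
  probe <- cur
  improvement <- (err1 - probe$value) / err1

  if (is.finite(improvement) && improvement > ctl$scale_tol) {
    scale_identified <- TRUE
    rho <- probe$par[1]; sigma <- probe$par[2]
    err <- objective(rho, sigma)    # recorded in the trace
  } else {
    scale_identified <- FALSE
    rho <- rho1; sigma <- ctl$sigma_ref
    err <- err1
  }
  weights <- cost_weights(10^(sigma + rho / 2), 10^(sigma - rho / 2))
  gain <- lqr_gain(linsys, weights)

  traj <- simulate_lqr(dyn, gain, x0 = x0, x_star = x_star,
                       t_final = n_steps / fs, dt = dt)
  # linear-plant fitted wrist displacement (the series the criterion used)
  xi <- .propagate_linear(A - B %*% gain$K, xi0, n_steps, dt)
  y_fit <- .wrist_y_from_xi(xi, x_star, geometry$lengths)
  y_fit <- y_fit - y_fit[1]

  trace <- do.call(rbind, trace_env$rows)
  colnames(trace) <- c("theta_p", "omega_p", "error")
  structure(list(weights = weights, error = err,
                 converged = nm_converged && is.finite(err),
                 scale_identified = scale_identified,
                 trace = trace,
                 scale_probe = list(theta_p = 10^(probe$par[2] + probe$par[1] / 2),
                                    omega_p = 10^(probe$par[2] - probe$par[1] / 2),
                                    error = probe$value, improvement = improvement),
                 gain = gain, linsys = linsys, geometry = geometry,
                 dynamics = dyn,
                 x0 = x0, x_star = x_star,
                 time = input$time[onset:n] - input$time[onset],
                 measured = y_meas, fitted_y = y_fit,
                 trajectory = traj, fps = fs,
                 control = ctl, subject = input$subject,
                 call = match.call()),
            class = "armioc")
}

#' @export
print.armioc <- function(x, ...) {
  cat("Inverse optimal control fit of arm flexion\n")
  cat(sprintf("  theta_p = %.6g, omega_p = %.6g (ratio %.4g)\n",
              x$weights$theta_p, x$weights$omega_p,
              x$weights$theta_p / x$weights$omega_p))
  cat(sprintf("  wrist trajectory error: %.4g m (l2 over %d samples)\n",
              x$error, length(x$measured)))
  cat(sprintf("  converged: %s; scale identified from data: %s\n",
              x$converged, x$scale_identified))
  invisible(x)
}

#' @export
coef.armioc <- function(object, ...) {
  c(theta_p = object$weights$theta_p, omega_p = object$weights$omega_p)
}

#' @export
fitted.armioc <- function(object, ...) object$fitted_y

#' @export
residuals.armioc <- function(object, ...) object$measured - object$fitted_y

#' @export
summary.armioc <- function(object, ...) {
  st <- stiffness(object)
  mo <- summarize_motion(object$trajectory)
  out <- list(fit = object, stiffness = st, motion = mo,
              rmse = sqrt(mean(residuals(object)^2)))
  class(out) <- "summary.armioc"
  out
}

#' @export
print.summary.armioc <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMSE: %.4g m\n", x$rmse))
  cat(sprintf("  movement: %.2f s, mean wrist speed %.3f m/s, peak %.3f m/s\n",
              x$motion$movement_time, x$motion$avg_wrist_speed,
              x$motion$peak_wrist_speed))
  cat(sprintf("  peak joint torques (N m): %s\n",
              paste(signif(x$motion$peak_torque, 4), collapse = ", ")))
  cat(sprintf("  principal velocity resistance tau* = %.4g along (%s)\n",
              x$stiffness$tau_star,
              paste(signif(x$stiffness$x2_star, 3), collapse = ", ")))
  invisible(x)
}

#' Predicted wrist trajectory for given weights
#'
#' Evaluates the fitted model's forward map at arbitrary penalty weights:
#' solves the LQR problem on the fit's linearized system and returns the
#' closed-loop vertical wrist displacement on the fit's time grid.
#'
#' @param object an `"armioc"` fit.
#' @param weights a [cost_weights()] object; default: the fitted weights.
#' @param ... unused.
#' @return numeric vector of wrist displacements (m) on `object$time`.
#' @export
predict.armioc <- function(object, weights = object$weights, ...) {
  g <- lqr_gain(object$linsys, weights)
  xi <- .propagate_linear(object$linsys$A - object$linsys$B %*% g$K,
                          object$x0 - object$x_star,
                          length(object$time) - 1L, 1 / object$fps)
  y <- .wrist_y_from_xi(xi, object$x_star, object$geometry$lengths)
  y - y[1]
}

#' @export
plot.armioc <- function(x, ...) {
  graphics::plot(x$time, x$measured, type = "l", col = "grey40",
                 xlab = "time since movement onset (s)",
                 ylab = "wrist vertical displacement (m)",
                 main = "Measured vs fitted wrist trajectory", ...)
  graphics::lines(x$time, x$fitted_y, col = "red3", lwd = 2)
  graphics::legend("bottomright", c("measured", "model"),
                   col = c("grey40", "red3"), lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate the fitted closed loop
#'
#' Re-simulates the fitted controller from the fit's initial state, on the
#' nonlinear plant by default, optionally with a sinusoidal state
#' perturbation in the feedback path.
#'
#' @param object an `"armioc"` fit.
#' @param nsim number of trajectories (they are identical unless a
#'   perturbation with different frequencies is given; kept for the generic's
#'   signature).
#' @param seed unused (the closed loop is deterministic); kept for the
#'   generic's signature.
#' @param plant `"nonlinear"` or `"linear"`.
#' @param t_final duration (s); default: the fit window.
#' @param kappa,freq_hz optional perturbation amplitude and frequency; see
#'   [simulate_perturbed()].
#' @param ... passed to the simulator.
#' @return an `"arm_trajectory"` (or a list of them if `nsim > 1`).
#' @export
simulate.armioc <- function(object, nsim = 1, seed = NULL,
                            plant = c("nonlinear", "linear"),
                            t_final = NULL, kappa = 0, freq_hz = 0, ...) {
  plant <- match.arg(plant)
  if (is.null(t_final)) t_final <- max(object$time)
  system <- if (plant == "nonlinear") object$dynamics else object$linsys
  one <- function() {
    if (kappa > 0) {
      simulate_perturbed(system, object$gain, kappa = kappa, freq_hz = freq_hz,
                         x0 = object$x0, x_star = object$x_star,
                         t_final = t_final, ...)
    } else {
      simulate_lqr(system, object$gain, x0 = object$x0, x_star = object$x_star,
                   t_final = t_final, exact = FALSE, ...)
    }
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' Scalar movement summaries of a trajectory
#'
#' Average and peak wrist speed over the movement interval (onset and offset
#' at 5\% of the peak wrist speed) and the peak absolute torque per joint.
#' For a stationary trajectory all summaries are zero.
#'
#' @param traj an `"arm_trajectory"`.
#' @param threshold movement detection threshold as a fraction of peak speed.
#' @return list with `avg_wrist_speed`, `peak_wrist_speed` (m/s),
#'   `peak_torque` (N m, per joint), `movement_time` (s), `onset`, `offset`.
#' @export
summarize_motion <- function(traj, threshold = 0.05) {
  stopifnot(inherits(traj, "arm_trajectory"))
  speed <- sqrt(rowSums(traj$wrist_velocity^2))
  peak <- max(speed)
  pk_tau <- apply(abs(traj$torque), 2, max)
  if (peak <= 0) {
    return(list(avg_wrist_speed = 0, peak_wrist_speed = 0,
                peak_torque = pk_tau, movement_time = 0,
                onset = NA_real_, offset = NA_real_))
  }
  moving <- which(speed >= threshold * peak)
  i0 <- moving[1]; i1 <- moving[length(moving)]
  mt <- traj$time[i1] - traj$time[i0]
  list(avg_wrist_speed = mean(speed[i0:i1]),
       peak_wrist_speed = peak,
       peak_torque = pk_tau,
       movement_time = mt,
       onset = traj$time[i0], offset = traj$time[i1])
}
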