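# Shared fixtures and independent oracles for the test suite.
# Everything here is deterministic; expensive objects are built once when the
# helper is sourced.

test_geometry <- arm_geometry()
test_dyn <- arm_dynamics(test_geometry)
test_dyn_free <- arm_dynamics(test_geometry, joint_limits(scale = 0))
test_lin <- linearize(test_dyn, c(pi, 0, 0))
gain_normal <- lqr_gain(test_lin, preset_weights("normal"))
gain_patient <- lqr_gain(test_lin, preset_weights("patient"))

# random interior state: angles well inside the default joint ranges,
# moderate velocities
random_state <- function() {
  c(runif(1, -0.3, 2.8), runif(1, 0.1, 2.3), runif(1, -0.3, 1.0),
    runif(3, -1, 1))
}

# --- oracle: hand-rolled RK4 integrator for a 1-dof pendulum --------------
# I thetadd = -G sin(theta) + tau(t)
rk4_pendulum <- function(I, G, tau, theta0, omega0, t_final, dt = 1e-4) {
  f <- function(t, y) c(y[2], (-G * sin(y[1]) + tau(t)) / I)
  n <- ceiling(t_final / dt)
  out_t <- seq(0, t_final, length.out = 201)
  out <- matrix(NA_real_, 201, 2)
  y <- c(theta0, omega0); t <- 0; j <- 1
  for (i in 0:n) {
    while (j <= 201 && out_t[j] <= t + 1e-12) { out[j, ] <- y; j <- j + 1 }
    k1 <- f(t, y); k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2); k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  list(time = out_t, theta = out[, 1], omega = out[, 2])
}

# --- oracle: forward kinematics by explicit rotation composition ----------
fk_rotation_oracle <- function(theta, lengths) {
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  down <- c(0, -1)
  p <- c(0, 0); R <- diag(2); out <- list()
  for (i in 1:3) {
    R <- R %*% rot(theta[i])
    p <- p + lengths[i] * drop(R %*% down)
    out[[i]] <- p
  }
  names(out) <- c("elbow", "wrist", "hand")
  out
}

# --- oracle: Welch statistic from the textbook formula --------------------
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# --- oracle: closed-loop quadratic cost by stiff ODE quadrature -----------
# J = int xi' Z xi + c' U c dt with c = -K xi on the linear plant; the
# augmented system is integrated adaptively so the fast closed-loop modes are
# resolved (a fixed 60 fps grid would not capture their control cost).
lqr_cost_ode <- function(A, B, K, Z, U, xi0, t_final = 15, rtol = 1e-10) {
  Acl <- A - B %*% K
  rhs <- function(t, y, p) {
    xi <- y[1:6]
    c_ <- -drop(K %*% xi)
    list(c(drop(Acl %*% xi), drop(t(xi) %*% Z %*% xi + t(c_) %*% U %*% c_)))
  }
  sol <- deSolve::lsoda(c(xi0, 0), c(0, t_final), rhs, parms = NULL,
                        rtol = rtol, atol = 1e-12)
  unname(sol[nrow(sol), 8])
}

# quick synthetic inputs reused across files (noiseless normal preset)
synth_normal_noiseless <- synthetic_recording(preset_weights("normal"),
                                              noise_sd = 0, seed = 1)
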