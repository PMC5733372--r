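# Infinite-horizon LQR: cost weights, continuous algebraic Riccati equation,
# feedback gain, and evaluation of the quadratic cost along trajectories.
#
# The regulator minimises J = integral( x' Z x + c' U c ) dt subject to
# dx/dt = A x + B c, with the state penalty Z = diag(theta_p, theta_p,
# theta_p, omega_p, omega_p, omega_p) and the control penalty U fixed to the
# identity. The stabilizing solution S of
#
#   S A + A' S - S B U^-1 B' S + Z = 0
#
# gives the optimal feedback c = -K x with K = U^-1 B' S.

#' Cost-functional penalty weights
#'
#' The two scalars parameterizing the state penalty: `theta_p` penalizes
#' squared joint-angle deviations and `omega_p` squared angular velocities.
#' Both must be strictly positive so the state penalty matrix is positive
#' definite. The control penalty is fixed to the identity, so only the
#' magnitudes of `theta_p` and `omega_p` relative to 1 (and to each other)
#' shape the controller; they are treated as dimensionless weights.
#'
#' @param theta_p penalty on squared joint angles (> 0).
#' @param omega_p penalty on squared angular velocities (> 0).
#' @return an object of class `"cost_weights"`.
#' @examples
#' cost_weights(12926292, 9315830)
#' @export
cost_weights <- function(theta_p, omega_p) {
  if (!is.finite(theta_p) || theta_p <= 0 || !is.finite(omega_p) || omega_p <= 0)
    stop("both penalty weights must be strictly positive and finite", call. = FALSE)
  structure(list(theta_p = theta_p, omega_p = omega_p), class = "cost_weights")
}

#' @export
print.cost_weights <- function(x, ...) {
  cat(sprintf("Cost weights: theta_p = %.7g, omega_p = %.7g (ratio %.4g)\n",
              x$theta_p, x$omega_p, x$theta_p / x$omega_p))
  invisible(x)
}

#' Reference cost-weight presets for the two study groups
#'
#' The fitted group-level penalty pairs reported for healthy controls
#' (`"normal"`: theta_p = 12,926,292, omega_p = 9,315,830) and for patients
#' with mild neuromotor abnormalities (`"patient"`: theta_p = 13,950,617,
#' omega_p = 5,245,197). The patient preset has a markedly lower omega_p
#' (less penalty on velocity, hence faster and jerkier movements) and a
#' higher theta_p.
#'
#' @param group `"normal"` or `"patient"`.
#' @return a [cost_weights()] object.
#' @export
preset_weights <- function(group = c("normal", "patient")) {
  group <- match.arg(group)
  switch(group,
         normal = cost_weights(12926292, 9315830),
         patient = cost_weights(13950617, 5245197))
}

#' State penalty matrix Z
#'
#' The diagonal 6 x 6 state penalty
#' `diag(theta_p, theta_p, theta_p, omega_p, omega_p, omega_p)`.
#'
#' @param weights a [cost_weights()] object.
#' @return a 6 x 6 diagonal matrix.
#' @export
penalty_matrix <- function(weights) {
  stopifnot(inherits(weights, "cost_weights"))
  diag(rep(c(weights$theta_p, weights$omega_p), each = 3))
}

#' Residual of the continuous algebraic Riccati equation
#'
#' @param S candidate symmetric solution.
#' @param A,B,Z,U system and cost matrices.
#' @return the residual matrix `S A + A' S - S B U^-1 B' S + Z`.
#' @export
care_residual <- function(S, A, B, Z, U) {
  G <- B %*% solve(U, t(B))
  S %*% A + t(A) %*% S - S %*% G %*% S + Z
}

#' Solve the continuous algebraic Riccati equation
#'
#' Computes the stabilizing symmetric solution of
#' `S A + A' S - S B U^-1 B' S + Z = 0` by the invariant-subspace method:
#' the stable eigenvectors of the Hamiltonian matrix
#' `rbind(cbind(A, -B U^-1 B'), cbind(-Z, -A'))` span `rbind(X1, X2)` and
#' `S = Re(X2 X1^-1)`. The solution is then polished by Newton steps (each a
#' Lyapunov solve) until the residual Frobenius norm is below
#' `tol * (1 + ||S||_F)`.
#'
#' @param A n x n state matrix; `(A, B)` must be stabilizable.
#' @param B n x m input matrix.
#' @param Z n x n positive semidefinite state penalty.
#' @param U m x m positive definite control penalty.
#' @param tol relative residual tolerance.
#' @return an object of class `"care_solution"`: list with the symmetric
#'   positive semidefinite `S`, the relative residual `residual`, and the
#'   closed-loop eigenvalues `closed_loop_eigenvalues`.
#' @examples
#' # scalar: 2S + S^2 - 1 = 0, stabilizing root sqrt(2) - 1
#' solve_care(matrix(-1), matrix(1), matrix(1), matrix(1))$S
#' @export
solve_care <- function(A, B, Z, U, tol = 1e-10) {
  A <- as.matrix(A); B <- as.matrix(B); Z <- as.matrix(Z); U <- as.matrix(U)
  n <- nrow(A)
  G <- B %*% solve(U, t(B))
  H <- rbind(cbind(A, -G), cbind(-Z, -t(A)))
  e <- eigen(H)
  stable <- Re(e$values) < 0
  if (sum(stable) != n) {
    # Hamiltonian eigenvalues come in +/- pairs unless an uncontrollable or
    # unobservable mode sits on the imaginary axis.
    imag_ax <- e$values[abs(Re(e$values)) < 1e-9]
    stop(sprintf(paste0("no stabilizing Riccati solution: %d stable Hamiltonian ",
                        "eigenvalues (need %d); near-imaginary modes: %s. ",
                        "Check that (A, B) is stabilizable."),
                 sum(stable), n,
                 paste(signif(imag_ax, 4), collapse = ", ")), call. = FALSE)
  }
  X <- e$vectors[, order(Re(e$values))[seq_len(n)], drop = FALSE]
  X1 <- X[seq_len(n), , drop = FALSE]
  sv <- svd(X1)$d
  if (sv[n] < 1e-12 * sv[1])
    stop("stable invariant subspace is degenerate; system not stabilizable",
         call. = FALSE)
  S <- Re(X[n + seq_len(n), , drop = FALSE] %*% solve(X1))
  S <- (S + t(S)) / 2
  # Newton polish: solve Acl' dS + dS Acl = -residual via the Kronecker form.
  In <- diag(n)
  relres <- function(S) {
    R <- S %*% A + t(A) %*% S - S %*% G %*% S + Z
    norm(R, "F") / (1 + norm(S, "F"))
  }
  for (i in 1:6) {
    R <- S %*% A + t(A) %*% S - S %*% G %*% S + Z
    if (norm(R, "F") < tol * (1 + norm(S, "F"))) break
    Acl <- A - G %*% S
    dS <- matrix(solve(kronecker(In, t(Acl)) + kronecker(t(Acl), In),
                       -as.vector(R)), n, n)
    S <- S + (dS + t(dS)) / 2
  }
  structure(list(S = S, residual = relres(S),
                 closed_loop_eigenvalues = eigen(A - G %*% S, only.values = TRUE)$values),
            class = "care_solution")
}

#' @export
print.care_solution <- function(x, ...) {
  cat(sprintf("Riccati solution (%d x %d), relative residual %.3g\n",
              nrow(x$S), ncol(x$S), x$residual))
  cat("closed-loop eigenvalue real parts:",
      paste(signif(Re(x$closed_loop_eigenvalues), 4), collapse = ", "), "\n")
  invisible(x)
}

#' LQR feedback gain
#'
#' Solves the Riccati equation for the given system and weights and returns
#' the optimal feedback gain `K = U^-1 B' S` (3 x 6 for the arm). The
#' closed-loop matrix `A - B K` is verified to be Hurwitz; failure signals a
#' wrong Riccati branch and is a hard error.
#'
#' @param system an `"arm_linsys"` object from [linearize()], or a plain list
#'   with elements `A` and `B`.
#' @param weights a [cost_weights()] object, or a full penalty matrix `Z`.
#' @param U control penalty (default identity).
#' @return an object of class `"lqr_gain"`: list with `K`, `S`, `weights`,
#'   `closed_loop_eigenvalues`, and the originating `system`.
#' @export
lqr_gain <- function(system, weights, U = NULL) {
  A <- system$A; B <- system$B
  if (is.null(U)) U <- diag(ncol(B))
  Z <- if (inherits(weights, "cost_weights")) penalty_matrix(weights) else as.matrix(weights)
  care <- solve_care(A, B, Z, U)
  K <- solve(U, t(B) %*% care$S)
  ev <- eigen(A - B %*% K, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("closed loop is not stable: wrong Riccati branch", call. = FALSE)
  structure(list(K = K, S = care$S,
                 weights = if (inherits(weights, "cost_weights")) weights else NULL,
                 residual = care$residual,
                 closed_loop_eigenvalues = ev,
                 system = system),
            class = "lqr_gain")
}

#' @export
print.lqr_gain <- function(x, ...) {
  cat("LQR gain K (torques = -K (x - x*)):\n")
  print(signif(x$K, 5))
  cat("slowest closed-loop mode:",
      signif(max(Re(x$closed_loop_eigenvalues)), 4), "1/s\n")
  invisible(x)
}

# Exact sampled closed-loop propagation of the linear plant in deviation
# coordinates xi = x - x*: xi(t_k) = expm(Acl t_k) xi0. Used by the estimator
# and the synthetic generator, where thousands of candidate trajectories are
# needed; exact for the LTI model at the sample instants (no integration
# error). Fast path: eigendecomposition of Acl, vectorized over the whole
# grid; falls back to matrix-exponential stepping if the eigenvector basis is
# ill-conditioned (defective or nearly defective Acl).
.propagate_linear <- function(Acl, xi0, n_steps, dt) {
  tgrid <- (0:n_steps) * dt
  e <- eigen(Acl)
  ok <- tryCatch({
    c0 <- solve(e$vectors, as.complex(xi0))
    rc <- rcond(abs(e$vectors))
    is.finite(rc) && rc > 1e-10
  }, error = function(err) FALSE)
  if (ok) {
    E <- exp(outer(e$values, tgrid))       # n x (n_steps+1)
    return(t(Re(e$vectors %*% (c0 * E))))
  }
  Phi <- as.matrix(Matrix::expm(Acl * dt))
  xi <- matrix(0, n_steps + 1L, length(xi0))
  xi[1, ] <- xi0
  for (i in seq_len(n_steps)) xi[i + 1, ] <- Phi %*% xi[i, ]
  xi
}

# Closed-loop LQR trajectory on the linear plant, exact at the samples.
# Returns an arm_trajectory in absolute coordinates; torques include the
# gravity-compensating offset c* so they are comparable with the nonlinear
# plant: c = c* - K (x - x*).
.simulate_lqr_linear <- function(linsys, K, x0, t_final, fs = 60) {
  n <- round(t_final * fs)
  xi <- .propagate_linear(linsys$A - linsys$B %*% K, x0 - linsys$x_star, n, 1 / fs)
  state <- sweep(xi, 2, linsys$x_star, "+")
  torque <- -xi %*% t(K)
  torque <- sweep(torque, 2, linsys$c_star, "+")
  .make_trajectory(seq(0, n) / fs, state, torque, linsys$geometry)
}

#' Simulate the LQR closed loop
#'
#' Runs the arm under the optimal feedback `c = c* - K (x - x*)` from a
#' starting posture, on either the nonlinear plant or the linearized plant.
#'
#' @param system an `"arm_dynamics"` or `"arm_linsys"` object.
#' @param gain an `"lqr_gain"` object (or a bare 3 x 6 matrix `K`).
#' @param x0 initial 6-state.
#' @param x_star target equilibrium (6-state or 3-posture); defaults to the
#'   linearization point when `system` is linear. Required for the nonlinear
#'   plant if `gain` is a bare matrix.
#' @param t_final duration (s).
#' @param dt output sampling interval (s).
#' @param exact for the linear plant only: propagate with the matrix
#'   exponential (exact at the samples, default) instead of adaptive
#'   integration.
#' @param ... passed to [simulate_arm()] (tolerances).
#' @return an `"arm_trajectory"`.
#' @export
simulate_lqr <- function(system, gain, x0, x_star = NULL, t_final = 10,
                         dt = 1 / 60, exact = inherits(system, "arm_linsys"), ...) {
  K <- if (inherits(gain, "lqr_gain")) gain$K else as.matrix(gain)
  if (inherits(system, "arm_linsys")) {
    if (is.null(x_star)) x_star <- system$x_star
    if (exact) return(.simulate_lqr_linear(system, K, x0, t_final, fs = 1 / dt))
    ctrl <- function(t, x) drop(system$c_star - K %*% (x - system$x_star))
    return(simulate_arm(system, ctrl, x0, t_final, dt, ...))
  }
  stopifnot(inherits(system, "arm_dynamics"))
  if (is.null(x_star)) {
    if (inherits(gain, "lqr_gain") && inherits(gain$system, "arm_linsys"))
      x_star <- gain$system$x_star
    else stop("'x_star' is required for the nonlinear plant", call. = FALSE)
  }
  x_star <- as.numeric(x_star)
  if (length(x_star) == 3L) x_star <- c(x_star, 0, 0, 0)
  c_star <- gravity_torque(system, x_star[1:3])
  ctrl <- function(t, x) drop(c_star - K %*% (x - x_star))
  simulate_arm(system, ctrl, x0, t_final, dt, ...)
}

#' Evaluate the quadratic cost along a trajectory
#'
#' Computes the running integrands and the total cost
#' `J = integral( x' Z x + c' U c ) dt` by trapezoidal quadrature, with the
#' states expressed as deviations from the target `x_star`. The state
#' integrand is reported in the mean-squared form
#' `I_v(t) = omega_p Omega(t)^2 + theta_p Theta(t)^2` with
#' `Omega^2 = omega1^2 + omega2^2 + omega3^2` and
#' `Theta^2 = theta1^2 + theta2^2 + theta3^2`; the control integrand is
#' `I_c(t) = c' U c`.
#'
#' @param traj an `"arm_trajectory"` with recorded torques.
#' @param weights a [cost_weights()] object.
#' @param x_star target state the deviations are measured from (6-state or
#'   3-posture; default zero).
#' @param U control penalty (default identity). The gravity-compensating
#'   torque at `x_star` is subtracted from the recorded torques so that the
#'   control cost measures feedback effort about the equilibrium.
#' @return list with total `J`, series `I_v`, `I_c`, `Omega`, `Theta`, and
#'   `time`.
#' @export
evaluate_cost <- function(traj, weights, x_star = rep(0, 6), U = diag(3)) {
  stopifnot(inherits(traj, "arm_trajectory"), inherits(weights, "cost_weights"))
  x_star <- as.numeric(x_star)
  if (length(x_star) == 3L) x_star <- c(x_star, 0, 0, 0)
  dev <- sweep(traj$state, 2, x_star)
  Theta2 <- rowSums(dev[, 1:3, drop = FALSE]^2)
  Omega2 <- rowSums(dev[, 4:6, drop = FALSE]^2)
  c_star <- tryCatch(gravity_torque(arm_dynamics(traj$geometry), x_star[1:3]),
                     error = function(e) c(0, 0, 0))
  ctl <- sweep(traj$torque, 2, c_star)
  I_c <- rowSums((ctl %*% U) * ctl)
  I_v <- weights$omega_p * Omega2 + weights$theta_p * Theta2
  list(J = .trapz(traj$time, I_v + I_c),
       I_v = I_v, I_c = I_c,
       Omega = sqrt(Omega2), Theta = sqrt(Theta2),
       time = traj$time)
}
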