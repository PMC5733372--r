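# Equations of motion of the planar three-link arm, their linearization, and
# numerical simulation.
#
# The dynamics are derived in absolute segment angles phi (where the mass
# matrix of a serial planar chain has the classical closed form) and mapped to
# the relative joint coordinates theta = inv(L) phi used by the rest of the
# package. Writing Mphi(phi) for the absolute-angle mass matrix, the relative
# mass matrix is Mrel = t(L) Mphi L and
#
#   Mrel(theta) domega/dt = tau + tau_limit - t(L) (cor(phi, dphi) + grav(phi))
#
# with cor the centrifugal/Coriolis vector (quadratic in the angular
# velocities) and grav the gravity torque about each absolute angle. The full
# first-order form M(x) dx/dt = r(x, c) has block-diagonal
# M = diag(I3, Mrel): the kinematic rows map omega to dtheta/dt exactly.

# pairwise coupling coefficients k12, k13, k23 (kg m^2)
.couplings <- function(g) {
  c(k12 = (g$masses[2] * g$com[2] + g$masses[3] * g$lengths[2]) * g$lengths[1],
    k13 = g$masses[3] * g$lengths[1] * g$com[3],
    k23 = g$masses[3] * g$lengths[2] * g$com[3])
}

# gravity torque coefficients: grav_i = gcoef_i * sin(phi_i)
.grav_coef <- function(g) {
  g$gravity * c(g$masses[1] * g$com[1] + (g$masses[2] + g$masses[3]) * g$lengths[1],
                g$masses[2] * g$com[2] + g$masses[3] * g$lengths[2],
                g$masses[3] * g$com[3])
}

.mass_phi <- function(g, phi, k) {
  M <- diag(c(g$inertia[1] + g$masses[1] * g$com[1]^2 +
                (g$masses[2] + g$masses[3]) * g$lengths[1]^2,
              g$inertia[2] + g$masses[2] * g$com[2]^2 +
                g$masses[3] * g$lengths[2]^2,
              g$inertia[3] + g$masses[3] * g$com[3]^2))
  M[1, 2] <- M[2, 1] <- k[1] * cos(phi[1] - phi[2])
  M[1, 3] <- M[3, 1] <- k[2] * cos(phi[1] - phi[3])
  M[2, 3] <- M[3, 2] <- k[3] * cos(phi[2] - phi[3])
  M
}

.coriolis_phi <- function(phi, dphi, k) {
  s12 <- sin(phi[1] - phi[2]); s13 <- sin(phi[1] - phi[3]); s23 <- sin(phi[2] - phi[3])
  c(k[1] * s12 * dphi[2]^2 + k[2] * s13 * dphi[3]^2,
    -k[1] * s12 * dphi[1]^2 + k[3] * s23 * dphi[3]^2,
    -k[2] * s13 * dphi[1]^2 - k[3] * s23 * dphi[2]^2)
}

#' Equations of motion of the three-link arm
#'
#' Assembles the nonlinear plant `M(x) dx/dt = r(x, c)` for the planar
#' three-link arm with gravity acting at each segment's centre of mass and
#' the smooth joint-limit torque of [joint_limit_torque()] added to the
#' forcing. States are `x = (theta1..theta3, omega1..omega3)`; controls `c`
#' are the three joint torques.
#'
#' @param geometry an [arm_geometry()] object.
#' @param limits a [joint_limits()] object; use `joint_limits(scale = 0)` for
#'   an unconstrained arm.
#' @return an object of class `"arm_dynamics"`: a list of closures
#'   \describe{
#'     \item{mass_matrix(x)}{the full 6 x 6 mass matrix (block diagonal:
#'       identity kinematic block, 3 x 3 dynamic block).}
#'     \item{forcing(x, tau)}{the 6-vector r(x, c).}
#'     \item{accel(x, tau)}{dx/dt = solve(M, r), the state derivative.}
#'     \item{force_components(x, tau)}{generalized force decomposition
#'       (applied, gravity, coriolis, constraint) in joint coordinates, for
#'       testing.}
#'     \item{energy(x)}{total mechanical energy (kinetic + gravitational,
#'       J), zero datum at the shoulder height.}
#'   }
#' @export
arm_dynamics <- function(geometry, limits = joint_limits()) {
  stopifnot(inherits(geometry, "arm_geometry"), inherits(limits, "joint_limits"))
  g <- geometry
  k <- .couplings(g)
  gc <- .grav_coef(g)
  L <- .Lmat; Lt <- t(.Lmat)

  mass_rel <- function(theta) {
    phi <- drop(L %*% theta)
    Lt %*% .mass_phi(g, phi, k) %*% L
  }
  components <- function(x, tau) {
    theta <- x[1:3]; omega <- x[4:6]
    phi <- drop(L %*% theta); dphi <- drop(L %*% omega)
    list(applied = tau,
         gravity = -drop(Lt %*% (gc * sin(phi))),
         coriolis = -drop(Lt %*% .coriolis_phi(phi, dphi, k)),
         constraint = joint_limit_torque(theta, limits))
  }
  forcing <- function(x, tau) {
    f <- components(x, tau)
    c(x[4:6], f$applied + f$gravity + f$coriolis + f$constraint)
  }
  accel <- function(x, tau) {
    r <- forcing(x, tau)
    c(r[1:3], solve(mass_rel(x[1:3]), r[4:6]))
  }
  mass_matrix <- function(x) {
    M <- diag(6)
    M[4:6, 4:6] <- mass_rel(x[1:3])
    M
  }
  energy <- function(x) {
    phi <- drop(L %*% x[1:3]); dphi <- drop(L %*% x[4:6])
    kin <- 0.5 * drop(t(dphi) %*% .mass_phi(g, phi, k) %*% dphi)
    pot <- -sum(gc * cos(phi))
    kin + pot
  }
  structure(list(geometry = g, limits = limits,
                 mass_matrix = mass_matrix, forcing = forcing, accel = accel,
                 force_components = components, energy = energy,
                 mass_rel = mass_rel),
            class = "arm_dynamics")
}

#' Gravity-compensating torque at a posture
#'
#' The joint torques that hold the arm stationary at `theta` (ignoring the
#' joint-limit torque, which is negligible at interior postures).
#'
#' @param dyn an [arm_dynamics()] object.
#' @param theta numeric(3) posture (rad).
#' @return numeric(3) torque (N m).
#' @export
gravity_torque <- function(dyn, theta) {
  stopifnot(inherits(dyn, "arm_dynamics"))
  phi <- drop(.Lmat %*% theta[1:3])
  drop(t(.Lmat) %*% (.grav_coef(dyn$geometry) * sin(phi)))
}

#' Linearize the arm about an equilibrium posture
#'
#' First-order model `d(x - x*)/dt = A (x - x*) + B (c - c*)` about a zero
#' velocity posture `x*` held by the gravity-compensating torque `c*`. The
#' Jacobians are evaluated analytically: at an equilibrium the Coriolis terms
#' are quadratic in the velocities so the velocity block vanishes, and
#'
#'   A = rbind(cbind(0, I), cbind(-Mrel^-1 t(L) diag(gcoef cos phi*) L, 0)),
#'   B = rbind(0, Mrel^-1).
#'
#' The smooth joint-limit torque is excluded from the linear model; it is a
#' nonlinear range-of-motion guard whose torque and slope are negligible at
#' interior postures, and the linear system is used only to derive the
#' controller.
#'
#' @param dyn an [arm_dynamics()] object.
#' @param x_star equilibrium state: a numeric(3) posture or a 6-state with
#'   zero velocities.
#' @return an object of class `"arm_linsys"` with elements `A` (6 x 6),
#'   `B` (6 x 3), `x_star` (6-state), `c_star` (3 torques), `geometry`.
#' @export
linearize <- function(dyn, x_star) {
  stopifnot(inherits(dyn, "arm_dynamics"))
  x_star <- as.numeric(x_star)
  if (length(x_star) == 3L) x_star <- c(x_star, 0, 0, 0)
  if (length(x_star) != 6L) stop("'x_star' must have 3 or 6 elements", call. = FALSE)
  if (any(abs(x_star[4:6]) > 1e-12))
    stop("linearization point must have zero velocities", call. = FALSE)
  g <- dyn$geometry
  phi <- drop(.Lmat %*% x_star[1:3])
  Mrel <- dyn$mass_rel(x_star[1:3])
  Mi <- tryCatch(solve(Mrel), error = function(e)
    stop("mass matrix is singular at the requested posture", call. = FALSE))
  Gjac <- t(.Lmat) %*% diag(.grav_coef(g) * cos(phi)) %*% .Lmat
  A <- rbind(cbind(matrix(0, 3, 3), diag(3)),
             cbind(-Mi %*% Gjac, matrix(0, 3, 3)))
  B <- rbind(matrix(0, 3, 3), Mi)
  structure(list(A = A, B = B, x_star = x_star,
                 c_star = gravity_torque(dyn, x_star[1:3]),
                 geometry = g),
            class = "arm_linsys")
}

#' @export
print.arm_linsys <- function(x, ...) {
  cat("Linearized arm model about posture (rad):",
      paste(signif(x$x_star[1:3], 4), collapse = ", "), "\n")
  ev <- eigen(x$A, only.values = TRUE)$values
  cat("open-loop eigenvalues (Re):", paste(signif(Re(ev), 4), collapse = ", "), "\n")
  invisible(x)
}

# Build an "arm_trajectory" object from a uniform time grid, state rows and
# torque rows, attaching Cartesian elbow/wrist positions and velocities.
.make_trajectory <- function(time, state, torque, geometry) {
  colnames(state) <- c("theta1", "theta2", "theta3", "omega1", "omega2", "omega3")
  colnames(torque) <- c("tau1", "tau2", "tau3")
  fkpos <- forward_kinematics(state, geometry)
  structure(list(time = time, state = state, torque = torque,
                 elbow = fkpos$elbow, wrist = fkpos$wrist,
                 wrist_velocity = .wrist_velocity(state, geometry),
                 geometry = geometry),
            class = "arm_trajectory")
}

#' @export
print.arm_trajectory <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("Arm trajectory: %d samples, t = %.3f .. %.3f s (%.4g fps)\n",
              n, x$time[1], x$time[n], 1 / diff(x$time[1:2])))
  cat(sprintf("wrist vertical range: %.3f .. %.3f m\n",
              min(x$wrist[, "y"]), max(x$wrist[, "y"])))
  invisible(x)
}

#' @export
as.data.frame.arm_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$state, x$torque,
             wrist_x = x$wrist[, "x"], wrist_y = x$wrist[, "y"],
             wrist_vx = x$wrist_velocity[, "x"], wrist_vy = x$wrist_velocity[, "y"])
}

#' Simulate the arm under a feedback controller
#'
#' Integrates the plant with `deSolve::lsoda` (adaptive, stiff-capable) and
#' samples the solution on a uniform grid, recording the applied torque at
#' each sample. Works on either the nonlinear plant (an [arm_dynamics()]
#' object) or the linearized plant (an [linearize()] result), in which case
#' the dynamics are `dx/dt = A (x - x*) + B (c - c*)`.
#'
#' @param system an `"arm_dynamics"` or `"arm_linsys"` object.
#' @param controller `function(t, x)` returning the three joint torques; or
#'   `NULL` for an unactuated arm.
#' @param x0 initial 6-state.
#' @param t_final final time (s).
#' @param dt output sampling interval (s), default 1/60 s.
#' @param rtol,atol integration tolerances.
#' @return an `"arm_trajectory"` object.
#' @export
simulate_arm <- function(system, controller, x0, t_final, dt = 1 / 60,
                         rtol = 1e-8, atol = 1e-10) {
  if (t_final <= 0) stop("'t_final' must be positive", call. = FALSE)
  x0 <- as.numeric(x0)
  stopifnot(length(x0) == 6L)
  if (is.null(controller)) controller <- function(t, x) c(0, 0, 0)
  times <- seq(0, t_final, by = dt)
  if (inherits(system, "arm_dynamics")) {
    geometry <- system$geometry
    rhs <- function(t, x, p) list(system$accel(x, controller(t, x)))
  } else if (inherits(system, "arm_linsys")) {
    geometry <- system$geometry
    A <- system$A; B <- system$B
    xs <- system$x_star; cs <- system$c_star
    rhs <- function(t, x, p) {
      list(drop(A %*% (x - xs) + B %*% (controller(t, x) - cs)))
    }
  } else stop("'system' must be an arm_dynamics or arm_linsys object", call. = FALSE)
  sol <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    stop(sprintf("integration failed at t = %.4f s", sol[nrow(sol), 1]), call. = FALSE)
  }
  state <- unname(sol[, 2:7, drop = FALSE])
  torque <- t(vapply(seq_along(times),
                     function(i) controller(times[i], state[i, ]),
                     numeric(3)))
  .make_trajectory(times, state, torque, geometry)
}
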