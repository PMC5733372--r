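# Arm geometry and planar forward kinematics.
#
# Angle convention used throughout the package: theta1 is the shoulder angle
# measured from the downward vertical (hanging rest = 0, flexion positive),
# theta2 and theta3 are the elbow and wrist angles relative to the proximal
# segment. The absolute segment angles are phi = L %*% theta with L the unit
# lower-triangular accumulation matrix, and a segment at absolute angle phi
# points along (sin phi, -cos phi): straight down at phi = 0, horizontal at
# phi = pi/2.

# phi = .Lmat %*% theta
.Lmat <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))

#' Three-link arm geometry
#'
#' Segment lengths, masses, centre-of-mass offsets and moments of inertia of
#' a planar upper-arm / forearm / hand chain. Masses and inertias are rarely
#' measured in a motion-capture session, so by default they are derived from
#' a total body mass using standard anthropometric fractions: segment masses
#' of 2.8\%, 1.6\% and 0.6\% of body mass, centres of mass at 43.6\%, 43.0\%
#' and 50.6\% of segment length from the proximal joint, and uniform-rod
#' moments of inertia about the centre of mass. All of these can be
#' overridden explicitly.
#'
#' @param lengths numeric(3), segment lengths in metres
#'   (upper arm, forearm, hand).
#' @param body_mass total body mass in kg, used for the default segment
#'   masses.
#' @param masses optional numeric(3) segment masses (kg); overrides the
#'   anthropometric defaults.
#' @param com optional numeric(3) centre-of-mass distances from the proximal
#'   joint (m).
#' @param inertia optional numeric(3) moments of inertia about each segment's
#'   centre of mass (kg m^2).
#' @param gravity gravitational acceleration (m/s^2).
#' @return an object of class `"arm_geometry"`.
#' @examples
#' geo <- arm_geometry()
#' geo
#' @export
arm_geometry <- function(lengths = c(0.31, 0.25, 0.18),
                         body_mass = 75,
                         masses = NULL,
                         com = NULL,
                         inertia = NULL,
                         gravity = 9.81) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3L || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("'lengths' must be three strictly positive finite values", call. = FALSE)
  if (!is.finite(body_mass) || body_mass <= 0)
    stop("'body_mass' must be strictly positive", call. = FALSE)
  if (is.null(masses)) masses <- body_mass * c(0.028, 0.016, 0.006)
  if (is.null(com)) com <- lengths * c(0.436, 0.430, 0.506)
  if (is.null(inertia)) inertia <- masses * lengths^2 / 12
  masses <- as.numeric(masses); com <- as.numeric(com); inertia <- as.numeric(inertia)
  if (any(masses <= 0)) stop("segment masses must be strictly positive", call. = FALSE)
  if (any(com <= 0) || any(com > lengths))
    stop("centre-of-mass offsets must satisfy 0 < com <= length", call. = FALSE)
  if (any(inertia <= 0)) stop("segment inertias must be strictly positive", call. = FALSE)
  if (!is.finite(gravity) || gravity < 0) stop("'gravity' must be >= 0", call. = FALSE)
  structure(
    list(lengths = lengths, masses = masses, com = com,
         inertia = inertia, gravity = gravity, body_mass = body_mass),
    class = "arm_geometry"
  )
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat("Planar 3-link arm geometry\n")
  df <- data.frame(
    segment = c("upper arm", "forearm", "hand"),
    length_m = x$lengths, mass_kg = x$masses,
    com_m = x$com, inertia_kgm2 = signif(x$inertia, 4)
  )
  print(df, row.names = FALSE)
  cat(sprintf("gravity: %.3f m/s^2\n", x$gravity))
  invisible(x)
}

#' Smooth joint-limit specification
#'
#' Defines a sigmoid restoring torque that is essentially zero strictly
#' inside each joint's range and rises smoothly (infinitely differentiably)
#' to `scale` beyond a bound, opposing the excursion. With `scale = 0` the
#' constraint is disabled.
#'
#' The default ranges place the rest posture (all angles zero) and the raised
#' target posture well inside every range so the constraint torque is
#' negligible along the nominal flexion movement and at the linearization
#' point.
#'
#' @param lower,upper numeric(3) joint range bounds in radians
#'   (shoulder, elbow, wrist).
#' @param steepness sigmoid steepness in 1/rad.
#' @param scale asymptotic constraint torque in N m; `0` disables the
#'   constraint.
#' @return an object of class `"joint_limits"`.
#' @export
joint_limits <- function(lower = c(-0.5, -0.2, -0.6),
                         upper = c(3.5, 2.8, 1.4),
                         steepness = 50,
                         scale = 25) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L || any(lower >= upper))
    stop("joint limits require lower < upper for all three joints", call. = FALSE)
  if (!is.finite(steepness) || steepness <= 0) stop("'steepness' must be > 0", call. = FALSE)
  if (!is.finite(scale) || scale < 0) stop("'scale' must be >= 0", call. = FALSE)
  structure(list(lower = lower, upper = upper,
                 steepness = steepness, scale = scale),
            class = "joint_limits")
}

#' @export
print.joint_limits <- function(x, ...) {
  cat("Joint limits (rad):\n")
  print(data.frame(joint = c("shoulder", "elbow", "wrist"),
                   lower = x$lower, upper = x$upper), row.names = FALSE)
  cat(sprintf("sigmoid steepness %.4g /rad, torque scale %.4g N m\n",
              x$steepness, x$scale))
  invisible(x)
}

#' Sigmoid joint-limit torque
#'
#' Restoring torque of the smooth range-of-motion constraint: for each joint
#' `scale * (plogis(k (lower - theta)) - plogis(k (theta - upper)))`, i.e.
#' positive (pushing the joint up) below the lower bound and negative above
#' the upper bound, with magnitude `scale/2` exactly at a bound and decaying
#' like `exp(-k d)` at distance `d` inside the range.
#'
#' @param theta joint angles: a numeric(3) vector or an n x 3 matrix.
#' @param limits a [joint_limits()] object.
#' @return torque with the same shape as `theta` (N m).
#' @export
joint_limit_torque <- function(theta, limits) {
  stopifnot(inherits(limits, "joint_limits"))
  if (limits$scale == 0) {
    return(if (is.matrix(theta)) array(0, dim(theta)) else numeric(length(theta)))
  }
  k <- limits$steepness
  f <- function(th, lo, hi) {
    limits$scale * (stats::plogis(k * (lo - th)) - stats::plogis(k * (th - hi)))
  }
  if (is.matrix(theta)) {
    out <- theta
    for (j in 1:3) out[, j] <- f(theta[, j], limits$lower[j], limits$upper[j])
    out
  } else {
    f(theta, limits$lower, limits$upper)
  }
}

#' Planar forward kinematics
#'
#' Positions of the elbow, wrist and hand tip in the sagittal plane, with the
#' shoulder fixed at the origin, the first coordinate horizontal (flexion
#' direction positive) and the second vertical (up positive). At the rest
#' posture (all angles zero) the arm hangs straight down, so the wrist sits
#' at `(0, -(l1 + l2))`.
#'
#' @param theta joint angles: numeric(3), a full 6-state vector (first three
#'   entries used), or an n x 3 (or n x 6) matrix of angle rows.
#' @param geometry an [arm_geometry()] object.
#' @return a list with `elbow`, `wrist`, `hand` — each a length-2 vector or an
#'   n x 2 matrix of (horizontal, vertical) coordinates in metres.
#' @export
forward_kinematics <- function(theta, geometry) {
  stopifnot(inherits(geometry, "arm_geometry"))
  vec <- !is.matrix(theta)
  th <- if (vec) matrix(theta[1:3], 1) else theta[, 1:3, drop = FALSE]
  phi <- th %*% t(.Lmat)
  l <- geometry$lengths
  ex <- l[1] * sin(phi[, 1]); ey <- -l[1] * cos(phi[, 1])
  wx <- ex + l[2] * sin(phi[, 2]); wy <- ey - l[2] * cos(phi[, 2])
  hx <- wx + l[3] * sin(phi[, 3]); hy <- wy - l[3] * cos(phi[, 3])
  out <- list(elbow = cbind(x = ex, y = ey),
              wrist = cbind(x = wx, y = wy),
              hand = cbind(x = hx, y = hy))
  if (vec) out <- lapply(out, function(m) m[1, ])
  out
}

# Planar wrist velocity from full state rows (n x 6): chain rule through the
# absolute angles.
.wrist_velocity <- function(state, geometry) {
  th <- state[, 1:3, drop = FALSE]
  om <- state[, 4:6, drop = FALSE]
  phi <- th %*% t(.Lmat)
  dphi <- om %*% t(.Lmat)
  l <- geometry$lengths
  vx <- l[1] * cos(phi[, 1]) * dphi[, 1] + l[2] * cos(phi[, 2]) * dphi[, 2]
  vy <- l[1] * sin(phi[, 1]) * dphi[, 1] + l[2] * sin(phi[, 2]) * dphi[, 2]
  cbind(x = vx, y = vy)
}
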