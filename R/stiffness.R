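# Principal directions of velocity resistance from the feedback gain.
#
# The feedback torque tau = K x splits into an angle block and a velocity
# block, tau = K1 x1 + K2 x2. The unit velocity direction most resisted by
# the controller maximizes ||K2 x2||; that maximum and maximizer are the
# leading singular value and right singular vector of K2. When K2 happens to
# be symmetric this coincides with its principal eigenvector; in general K2
# is not symmetric and only the SVD solves the stated maximization, so both
# the singular spectrum and (for reference) the eigen decomposition are
# reported.

#' Partition a feedback gain into angle and velocity blocks
#'
#' @param K a 3 x 6 gain matrix (or an `"lqr_gain"` object).
#' @return list with `K1` (columns 1-3, angle feedback) and `K2`
#'   (columns 4-6, velocity feedback).
#' @export
partition_gain <- function(K) {
  if (inherits(K, "lqr_gain")) K <- K$K
  K <- as.matrix(K)
  if (!all(dim(K) == c(3, 6)))
    stop("gain must be 3 x 6 (three torques, six states)", call. = FALSE)
  list(K1 = K[, 1:3, drop = FALSE], K2 = K[, 4:6, drop = FALSE])
}

#' Principal velocity resistance of a gain's velocity block
#'
#' Solves `tau* = max_{||x2|| = 1} ||K2 x2||` exactly via the singular value
#' decomposition: `tau*` is the largest singular value of `K2` and `x2*` the
#' corresponding right singular vector (defined up to sign; the convention
#' here makes its largest-magnitude component positive). The largest
#' component of `x2*` indicates the joint velocity that is resisted the most.
#'
#' @param K2 3 x 3 velocity-feedback block.
#' @return list with `tau_star`, the unit vector `x2_star`, the full singular
#'   `spectrum` (descending), and the eigenvalues `eigen_values` of `K2` for
#'   reference.
#' @export
principal_resistance <- function(K2) {
  K2 <- as.matrix(K2)
  if (!all(dim(K2) == c(3, 3)) || any(!is.finite(K2)))
    stop("'K2' must be a finite 3 x 3 matrix", call. = FALSE)
  sv <- svd(K2)
  x2 <- sv$v[, 1]
  x2 <- x2 * sign(x2[which.max(abs(x2))])
  list(tau_star = sv$d[1], x2_star = x2, spectrum = sv$d,
       eigen_values = eigen(K2, only.values = TRUE)$values)
}

#' Stiffness structure of a fitted controller
#'
#' Gain partition and principal velocity-resistance analysis.
#'
#' @param object an `"armioc"` fit, an `"lqr_gain"`, or a bare 3 x 6 matrix.
#' @param ... unused.
#' @return an object of class `"stiffness_report"`: list with `K1`, `K2`,
#'   `tau_star`, `x2_star`, `spectrum`, `eigen_values`.
#' @export
stiffness <- function(object, ...) UseMethod("stiffness")

#' @export
stiffness.armioc <- function(object, ...) stiffness(object$gain)

#' @export
stiffness.lqr_gain <- function(object, ...) stiffness(object$K)

#' @export
stiffness.default <- function(object, ...) {
  p <- partition_gain(object)
  pr <- principal_resistance(p$K2)
  structure(c(p, pr), class = "stiffness_report")
}

#' @export
print.stiffness_report <- function(x, ...) {
  cat("Velocity-resistance analysis of the feedback gain\n")
  cat(sprintf("tau* = %.6g (singular spectrum: %s)\n",
              x$tau_star, paste(signif(x$spectrum, 5), collapse = ", ")))
  cat("principal resisted velocity direction x2* (shoulder, elbow, wrist):\n")
  print(signif(x$x2_star, 5))
  invisible(x)
}
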