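# YAML configuration for command-line / batch use.
#
# All angles in the config file are in degrees (the CLI boundary); they are
# converted to radians here. Everything is optional; omitted sections fall
# back to the package defaults.

#' Read an analysis configuration from YAML
#'
#' Supported top-level keys (all optional):
#' \describe{
#'   \item{body_mass}{subject body mass (kg).}
#'   \item{lengths}{three segment lengths (m), overriding measured ones.}
#'   \item{gravity}{gravitational acceleration (m/s^2).}
#'   \item{joint_limits}{`lower_deg`, `upper_deg` (length 3), `steepness`
#'     (1/rad), `scale` (N m).}
#'   \item{target_deg}{target posture (3 joint angles, degrees).}
#'   \item{static_window}{static window length (s).}
#'   \item{fit}{entries merged into the `control` list of [armioc()].}
#'   \item{solver}{`rtol`, `atol` integration tolerances.}
#'   \item{perturbation}{`kappa`, `freqs_hz` (vector or `from`/`to`/`by`),
#'     `t_max`, `f_max` for [frequency_sweep()].}
#' }
#'
#' @param path YAML file.
#' @return a list of class `"arm_config"` with elements `body_mass`,
#'   `lengths`, `gravity`, `limits` ([joint_limits()]), `x_star` (radians, or
#'   `NULL`), `static_window`, `fit`, `solver`, `perturbation`.
#' @export
read_arm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  lim <- cfg$joint_limits
  limits <- if (is.null(lim)) joint_limits() else {
    d <- joint_limits()
    joint_limits(
      lower = if (!is.null(lim$lower_deg)) lim$lower_deg * pi / 180 else d$lower,
      upper = if (!is.null(lim$upper_deg)) lim$upper_deg * pi / 180 else d$upper,
      steepness = if (!is.null(lim$steepness)) lim$steepness else d$steepness,
      scale = if (!is.null(lim$scale)) lim$scale else d$scale)
  }
  pert <- cfg$perturbation
  if (!is.null(pert$freqs_hz) && is.list(pert$freqs_hz)) {
    f <- pert$freqs_hz
    pert$freqs_hz <- seq(f$from, f$to, by = if (is.null(f$by)) 1 else f$by)
  }
  structure(list(
    body_mass = if (is.null(cfg$body_mass)) 75 else cfg$body_mass,
    lengths = cfg$lengths,
    gravity = if (is.null(cfg$gravity)) 9.81 else cfg$gravity,
    limits = limits,
    x_star = if (!is.null(cfg$target_deg)) cfg$target_deg * pi / 180 else NULL,
    static_window = if (is.null(cfg$static_window)) 5 else cfg$static_window,
    fit = if (is.null(cfg$fit)) list() else cfg$fit,
    solver = utils::modifyList(list(rtol = 1e-8, atol = 1e-10),
                               if (is.null(cfg$solver)) list() else cfg$solver),
    perturbation = pert
  ), class = "arm_config")
}
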