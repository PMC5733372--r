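# Equations of motion of the three-link arm: conservation laws, reductions to
# known systems, and kinematic consistency.

test_that("no gravity, no torque, no constraint: the arm stays put", {
  g0 <- arm_geometry(gravity = 0)
  dyn <- arm_dynamics(g0, joint_limits(scale = 0))
  x0 <- c(0.4, 0.7, -0.1, 0, 0, 0)
  expect_equal(dyn$accel(x0, c(0, 0, 0)), rep(0, 6))
  traj <- simulate_arm(dyn, NULL, x0, t_final = 1)
  expect_lt(max(abs(sweep(traj$state, 2, x0))), 1e-9)
})

test_that("passive swing conserves mechanical energy", {
  set.seed(42)
  for (i in 1:5) {
    x0 <- random_state()
    traj <- simulate_arm(test_dyn_free, NULL, x0, t_final = 5)
    E <- apply(traj$state, 1, test_dyn_free$energy)
    expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-3)
  }
})

test_that("dynamic mass-matrix block is symmetric positive definite", {
  set.seed(7)
  for (i in 1:100) {
    x <- random_state()
    M <- test_dyn$mass_matrix(x)
    expect_equal(M[1:3, 1:3], diag(3))        # kinematic rows: dtheta/dt = omega
    Md <- M[4:6, 4:6]
    expect_equal(Md, t(Md))
    expect_true(all(eigen(Md, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("with distal joints locked, joint 1 follows the single-pendulum equation", {
  # lock elbow and wrist with a stiff, narrow constraint
  lock <- joint_limits(lower = c(-10, -1e-3, -1e-3), upper = c(10, 1e-3, 1e-3),
                       steepness = 2000, scale = 500)
  dyn <- arm_dynamics(test_geometry, lock)
  g <- test_geometry
  # straightened-chain pendulum about the shoulder
  d1 <- g$com[1]; d2 <- g$lengths[1] + g$com[2]; d3 <- g$lengths[1] + g$lengths[2] + g$com[3]
  I_tot <- sum(g$inertia) + g$masses[1] * d1^2 + g$masses[2] * d2^2 + g$masses[3] * d3^2
  G_tot <- g$gravity * (g$masses[1] * d1 + g$masses[2] * d2 + g$masses[3] * d3)
  tau1 <- function(t) 2 * sin(3 * t)
  ctrl <- function(t, x) c(tau1(t), 0, 0)
  traj <- simulate_arm(dyn, ctrl, c(0.3, 0, 0, 0, 0, 0), t_final = 2)
  oracle <- rk4_pendulum(I_tot, G_tot, tau1, 0.3, 0, 2)
  th1 <- approx(traj$time, traj$state[, 1], oracle$time)$y
  expect_lt(max(abs(th1 - oracle$theta)), 2e-3)
  # the locked joints barely move
  expect_lt(max(abs(traj$state[, 2:3])), 5e-3)
})

test_that("joint-limit torque is a centred sigmoid", {
  lim <- joint_limits()
  mid <- (lim$lower + lim$upper) / 2
  expect_lt(max(abs(joint_limit_torque(mid, lim))), 1e-3 * lim$scale)
  # just beyond the upper elbow bound: restoring (negative), matches formula
  th <- mid; th[2] <- lim$upper[2] + 0.05
  tq <- joint_limit_torque(th, lim)
  expect_lt(tq[2], 0)
  direct <- lim$scale * (plogis(lim$steepness * (lim$lower[2] - th[2])) -
                           plogis(lim$steepness * (th[2] - lim$upper[2])))
  expect_equal(tq[2], direct)
  # monotone in angle across the range
  grid <- seq(lim$lower[2] - 0.3, lim$upper[2] + 0.3, length.out = 100)
  tq2 <- joint_limit_torque(cbind(0, grid, 0), lim)[, 2]
  expect_true(all(diff(tq2) <= 1e-12))
  # disabled constraint
  off <- joint_limits(scale = 0)
  expect_equal(joint_limit_torque(c(10, 10, 10), off), c(0, 0, 0))
})

test_that("forward kinematics matches the rotation-composition oracle", {
  l <- test_geometry$lengths
  rest <- forward_kinematics(c(0, 0, 0), test_geometry)
  expect_equal(unname(rest$wrist), c(0, -(l[1] + l[2])))
  flex <- forward_kinematics(c(pi / 2, 0, 0), test_geometry)
  expect_equal(unname(flex$wrist), c(l[1] + l[2], 0))
  set.seed(11)
  for (i in 1:20) {
    th <- runif(3, -pi, pi)
    fk <- forward_kinematics(th, test_geometry)
    or <- fk_rotation_oracle(th, l)
    for (j in c("elbow", "wrist", "hand"))
      expect_equal(unname(fk[[j]]), unname(or[[j]]), tolerance = 1e-12)
    # chain-length invariant
    expect_equal(sqrt(sum((fk$wrist - fk$elbow)^2)), l[2])
  }
})

test_that("simulation is stationary at a held equilibrium and grid-independent", {
  x_eq <- c(0.8, 0.5, 0.2, 0, 0, 0)
  c_eq <- gravity_torque(test_dyn_free, x_eq[1:3])
  traj <- simulate_arm(test_dyn_free, function(t, x) c_eq, x_eq, t_final = 2)
  expect_lt(max(abs(sweep(traj$state, 2, x_eq))), 1e-6)
  # halving the output step does not change the sampled solution
  ctrl <- function(t, x) c(sin(t), 0, 0)
  t1 <- simulate_arm(test_dyn_free, ctrl, x_eq, t_final = 1, dt = 1 / 60)
  t2 <- simulate_arm(test_dyn_free, ctrl, x_eq, t_final = 1, dt = 1 / 120)
  expect_lt(max(abs(t1$state - t2$state[seq(1, 121, by = 2), ])), 1e-6)
})

test_that("linear-plant simulation matches the matrix-exponential solution", {
  K <- gain_normal$K
  x0 <- test_lin$x_star + c(-0.2, 0.1, -0.05, 0, 0, 0)
  ctrl <- function(t, x) drop(test_lin$c_star - K %*% (x - test_lin$x_star))
  traj <- simulate_arm(test_lin, ctrl, x0, t_final = 2, dt = 1 / 60,
                       rtol = 1e-10, atol = 1e-12)
  Acl <- test_lin$A - test_lin$B %*% K
  xi0 <- x0 - test_lin$x_star
  for (i in c(2, 31, 61, 121)) {
    oracle <- drop(as.matrix(Matrix::expm(Acl * traj$time[i])) %*% xi0) +
      test_lin$x_star
    expect_lt(max(abs(traj$state[i, ] - oracle)), 1e-6)
  }
})

test_that("degenerate geometry is rejected with a diagnostic", {
  expect_error(arm_geometry(lengths = c(0, 0.25, 0.18)), "positive")
  expect_error(arm_geometry(masses = c(0, 1, 1)), "positive")
  expect_error(arm_geometry(com = c(1, 0.1, 0.1)), "com")
})
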