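# Riccati solver, gain, and quadratic cost evaluation.

test_that("scalar Riccati equation has the closed-form stabilizing root", {
  # 2S + S^2 - 1 = 0 -> S = sqrt(2) - 1
  sol <- solve_care(matrix(-1), matrix(1), matrix(1), matrix(1))
  expect_equal(sol$S[1, 1], sqrt(2) - 1, tolerance = 1e-10)
  K <- solve(matrix(1), t(matrix(1)) %*% sol$S)
  expect_equal(K[1, 1], sqrt(2) - 1, tolerance = 1e-10)
})

test_that("double integrator gives the textbook gain [1, sqrt(3)]", {
  A <- rbind(c(0, 1), c(0, 0)); B <- matrix(c(0, 1), 2)
  sol <- solve_care(A, B, diag(2), matrix(1))
  K <- drop(t(B) %*% sol$S)
  expect_equal(K, c(1, sqrt(3)), tolerance = 1e-10)
})

test_that("jointly scaling Z and U leaves the gain unchanged", {
  Z <- penalty_matrix(preset_weights("normal")); U <- diag(3)
  K1 <- solve(U, t(test_lin$B) %*% solve_care(test_lin$A, test_lin$B, Z, U)$S)
  a <- 7.3
  K2 <- solve(a * U, t(test_lin$B) %*%
                solve_care(test_lin$A, test_lin$B, a * Z, a * U)$S)
  expect_equal(K1, K2, tolerance = 1e-8)
})

test_that("penalty matrix has the stated diagonal structure", {
  expect_equal(penalty_matrix(cost_weights(1, 1)), diag(6))
  Z <- penalty_matrix(preset_weights("patient"))
  expect_equal(diag(Z), rep(c(13950617, 5245197), each = 3))
  expect_true(all(Z[upper.tri(Z)] == 0))
  expect_error(cost_weights(-1, 2), "positive")
  expect_error(cost_weights(1, 0), "positive")
})

test_that("preset controllers solve the Riccati equation and stabilize the arm", {
  for (gain in list(gain_normal, gain_patient)) {
    S <- gain$S
    R <- care_residual(S, test_lin$A, test_lin$B,
                       penalty_matrix(gain$weights), diag(3))
    expect_lt(norm(R, "F"), 1e-8 * (1 + norm(S, "F")))
    expect_equal(S, t(S), tolerance = 1e-12)
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > -1e-6))
    expect_true(all(Re(gain$closed_loop_eigenvalues) < 0))
    expect_equal(gain$K, t(test_lin$B) %*% S, tolerance = 1e-12)  # U = I
  }
})

test_that("an unstabilizable pair is rejected with a diagnostic", {
  # unstable mode not reachable from the input
  A <- diag(c(1, -1)); B <- matrix(c(0, 1), 2)
  expect_error(solve_care(A, B, diag(2), matrix(1)), "stabilizable")
})

test_that("closed-loop cost matches the Riccati cost-to-go x0' S x0", {
  set.seed(3)
  for (gain in list(gain_normal, gain_patient)) {
    for (i in 1:5) {
      xi0 <- c(runif(3, -1, 1), runif(3, -0.3, 0.3))
      x0 <- test_lin$x_star + xi0
      traj <- simulate_lqr(test_lin, gain, x0 = x0, t_final = 20, dt = 1 / 120)
      cost <- evaluate_cost(traj, gain$weights, x_star = test_lin$x_star)
      expect_equal(cost$J, drop(t(xi0) %*% gain$S %*% xi0), tolerance = 0.01)
    }
  }
})

test_that("increasing the velocity penalty slows the peak movement speed", {
  x0 <- rep(0, 6)   # rest; target is the raised posture
  peaks <- vapply(c(2e6, 5e6, 1e7, 3e7, 1e8), function(wp) {
    g <- lqr_gain(test_lin, cost_weights(12926292, wp))
    traj <- simulate_lqr(test_lin, g, x0 = x0, t_final = 10)
    max(sqrt(rowSums(traj$state[, 4:6]^2)))
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("evaluate_cost integrates the stated integrands", {
  # stationary at the target with gravity-compensating torque: J = 0
  n <- 61; xs <- c(pi, 0, 0, 0, 0, 0)
  cs <- gravity_torque(test_dyn, xs[1:3])
  stat <- armioc:::.make_trajectory(seq(0, 1, length.out = n),
                                    matrix(rep(xs, each = n), n),
                                    matrix(rep(cs, each = n), n),
                                    test_geometry)
  cost0 <- evaluate_cost(stat, cost_weights(2, 3), x_star = xs)
  expect_equal(cost0$J, 0, tolerance = 1e-12)
  # constant unit deviation on all six states over 1 s, gravity-compensating
  # torque: I_v = theta_p * Theta^2 + omega_p * Omega^2 = 2*3 + 3*3 = 15
  dev <- armioc:::.make_trajectory(seq(0, 1, length.out = n),
                                   matrix(rep(xs + 1, each = n), n),
                                   matrix(rep(cs, each = n), n),
                                   test_geometry)
  cost1 <- evaluate_cost(dev, cost_weights(2, 3), x_star = xs)
  expect_equal(cost1$J, 15, tolerance = 1e-12)
  expect_equal(unname(cost1$Theta), rep(sqrt(3), n))
  expect_equal(unname(cost1$Omega), rep(sqrt(3), n))
  expect_equal(cost1$I_c, rep(0, n))
})
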