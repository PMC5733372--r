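# The inverse optimal control estimator and its S3 interface.

test_that("trajectory error is the l2 norm of the wrist-height difference", {
  y <- sin(seq(0, 1, length.out = 50))
  expect_equal(trajectory_error(y, y), 0)
  expect_equal(trajectory_error(y + 0.3, y), 0.3 * sqrt(50))
  set.seed(2)
  a <- rnorm(80); b <- rnorm(80)
  expect_equal(trajectory_error(a, b), sqrt(sum((a - b)^2)))
  expect_error(trajectory_error(a, b[1:40]), "resample")
  # trajectory objects: grid checks and overlap handling
  t1 <- simulate_lqr(test_lin, gain_normal, x0 = rep(0, 6), t_final = 2)
  t2 <- simulate_lqr(test_lin, gain_normal, x0 = rep(0, 6), t_final = 2,
                     dt = 1 / 30)
  expect_error(trajectory_error(t1, t2), "resample")
  expect_equal(trajectory_error(t1, t1), 0)
})

test_that("summarize_motion reports movement-window speeds and peak torques", {
  # stationary trajectory: all zero
  n <- 31; xs <- c(0.3, 0.2, 0.1, 0, 0, 0)
  stat <- armioc:::.make_trajectory(seq(0, 1, length.out = n),
                                    matrix(rep(xs, each = n), n),
                                    matrix(0, n, 3), test_geometry)
  s <- summarize_motion(stat)
  expect_equal(s$avg_wrist_speed, 0)
  expect_equal(s$peak_wrist_speed, 0)
  expect_equal(unname(s$peak_torque), c(0, 0, 0))
  # rigid rotation at constant omega: wrist speed is exactly (l1+l2)*omega
  om <- 0.8; tt <- seq(0, 1, length.out = n)
  st <- cbind(om * tt, 0, 0, rep(om, n), 0, 0)
  rot <- armioc:::.make_trajectory(tt, st, matrix(1.5, n, 3), test_geometry)
  v <- (test_geometry$lengths[1] + test_geometry$lengths[2]) * om
  s2 <- summarize_motion(rot)
  expect_equal(s2$avg_wrist_speed, v, tolerance = 1e-12)
  expect_equal(s2$peak_wrist_speed, v, tolerance = 1e-12)
  expect_equal(unname(s2$peak_torque), c(1.5, 1.5, 1.5))
})

test_that("the fit is deterministic and its trace invariant holds", {
  syn <- synthetic_recording(preset_weights("normal"), noise_sd = 0.005,
                             seed = 5, duration = 8)
  f1 <- armioc(syn$recording)
  f2 <- armioc(syn$recording)
  expect_identical(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
  # reported error is attained and is the best of the reported branch
  expect_equal(f1$error, min(f1$trace[, "error"]))
  expect_true(f1$converged)
})

test_that("noiseless weights are recovered at desk scale", {
  # one non-preset weight pair, full synth -> ingest -> fit round trip
  true_w <- cost_weights(3.2e6, 1.4e6)
  syn <- synthetic_recording(true_w, noise_sd = 0, seed = 2, duration = 8)
  fit <- armioc(syn$recording)
  w <- coef(fit)
  expect_lt(abs(w["theta_p"] / true_w$theta_p - 1), 0.10)
  expect_lt(abs(w["omega_p"] / true_w$omega_p - 1), 0.10)
  expect_lt(abs((w["theta_p"] / w["omega_p"]) /
                  (true_w$theta_p / true_w$omega_p) - 1), 0.05)
  expect_true(fit$scale_identified)
  # S3 surface behaves
  expect_length(fitted(fit), length(fit$measured))
  expect_equal(residuals(fit), fit$measured - fitted(fit))
  expect_lt(sqrt(mean(residuals(fit)^2)), 1e-3)
  expect_s3_class(fit$trajectory, "arm_trajectory")
  p <- predict(fit, preset_weights("normal"))
  expect_length(p, length(fit$measured))
})

test_that("identifiability holds for random subjects at task-realistic ratios", {
  set.seed(31)
  specs <- data.frame(theta_p = 10^runif(5, 5.5, 7.5),
                      ratio = runif(5, 0.7, 4))
  for (i in 1:5) {
    tw <- cost_weights(specs$theta_p[i], specs$theta_p[i] / specs$ratio[i])
    syn <- synthetic_recording(tw, noise_sd = 0, seed = 100 + i, duration = 8)
    w <- coef(armioc(syn$recording))
    expect_lt(abs(w["theta_p"] / tw$theta_p - 1), 0.10)
    expect_lt(abs(w["omega_p"] / tw$omega_p - 1), 0.10)
  }
})

test_that("the optimum dominates a coarse log-grid search", {
  syn <- synthetic_recording(preset_weights("normal"), noise_sd = 0, seed = 2,
                             duration = 8)
  input <- prepare_input(syn$recording)
  fit <- armioc(input)
  # rebuild the fit's criterion on an 11 x 11 grid over [1e3, 1e9]^2
  lp <- armioc:::.make_lowpass(input$fps, fit$control$cutoff_hz)
  onset <- which(input$time >= 5)[1]; n <- length(input$time)
  ym <- lp(input$wrist_y[onset:n] - input$wrist_y[onset])
  A <- fit$linsys$A; B <- fit$linsys$B
  xi0 <- fit$x0 - fit$x_star
  grid <- 10^seq(3, 9, length.out = 11)
  errs <- outer(grid, grid, Vectorize(function(tp, wp) {
    S <- solve_care(A, B, diag(rep(c(tp, wp), each = 3)), diag(3))$S
    xi <- armioc:::.propagate_linear(A - B %*% (t(B) %*% S), xi0,
                                     n - onset, 1 / input$fps)
    y <- armioc:::.wrist_y_from_xi(xi, fit$x_star, fit$geometry$lengths)
    sqrt(sum((lp(y - y[1]) - ym)^2))
  }))
  expect_lte(fit$error, min(errs))
})

test_that("fit failure modes give diagnostics", {
  syn <- synthetic_recording(preset_weights("normal"), noise_sd = 0, seed = 2,
                             duration = 8)
  input <- prepare_input(syn$recording)
  input$static_window <- 20     # leaves no movement window
  expect_error(armioc(input), "movement window")
})
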