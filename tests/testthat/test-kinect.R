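# Skeleton I/O, Fourier resampling, scaling and angle extraction.

make_static_recording <- function(l = c(0.30, 0.26, 0.08), n = 150, fps = 30,
                                  noise = 0, seed = 1) {
  theta <- matrix(0, n, 3)
  fk <- forward_kinematics(theta, arm_geometry(lengths = l))
  joints <- list(
    shoulder = cbind(x = rep(0, n), y = rep(0, n), z = rep(0, n)),
    elbow = cbind(x = fk$elbow[, "x"], y = fk$elbow[, "y"], z = rep(0, n)),
    wrist = cbind(x = fk$wrist[, "x"], y = fk$wrist[, "y"], z = rep(0, n)),
    hand = cbind(x = fk$hand[, "x"], y = fk$hand[, "y"], z = rep(0, n)))
  if (noise > 0) {
    joints <- withr::with_seed(seed, lapply(joints, function(m)
      m + matrix(rnorm(length(m), 0, noise), nrow(m))))
  }
  skeleton_recording((seq_len(n) - 1) / fps, joints, fps = fps)
}

test_that("CSV round trip preserves coordinates", {
  rec <- synth_normal_noiseless$recording
  path <- withr::local_tempfile(fileext = ".csv")
  write_skeleton(rec, path)
  back <- read_skeleton(path)
  expect_equal(length(back$time), length(rec$time))
  for (j in c("shoulder", "elbow", "wrist", "hand"))
    expect_lt(max(abs(back$joints[[j]] - rec$joints[[j]])), 1e-9)
})

test_that("malformed recordings are rejected or repaired with a message", {
  rec <- make_static_recording(n = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_skeleton(rec, path)
  df <- read.csv(path)
  # missing wrist rows -> error naming the joint
  write.csv(df[df$joint != "wrist", ], path, row.names = FALSE)
  expect_error(read_skeleton(path), "wrist")
  # unknown joint names are ignored with a warning
  df2 <- df
  df2$joint[df2$joint == "hand"][1] <- "noise_marker"
  write.csv(df2, path, row.names = FALSE)
  expect_warning(expect_error(read_skeleton(path), "hand"), "noise_marker")
})

test_that("Fourier resampling doubles the frame count and is exact for tones", {
  rec <- make_static_recording(n = 150)
  up <- resample_recording(rec)
  expect_equal(length(up$time), 300)
  expect_equal(up$fps, 60)
  # constant channels stay constant
  expect_lt(max(abs(up$joints$wrist[, "x"] - rec$joints$wrist[1, "x"])), 1e-12)
  # a band-limited tone sampled over integer periods is reproduced exactly
  fs <- 30; t30 <- (0:149) / fs
  tone <- function(t) sin(2 * pi * 2 * t + 0.4)
  rec$joints$wrist[, "z"] <- tone(t30)
  up <- resample_recording(rec)
  t60 <- (0:299) / 60
  expect_lt(max(abs(up$joints$wrist[, "z"] - tone(t60))[20:280]), 1e-6)
  # energy is preserved for band-limited content (Parseval)
  x <- tone(t30); y <- up$joints$wrist[, "z"]
  expect_equal(mean(y^2), mean(x^2), tolerance = 1e-6)
})

test_that("non-uniform recordings are rejected with advice", {
  rec <- make_static_recording(n = 20)
  rec$time[10] <- rec$time[10] + 0.01
  expect_error(resample_recording(rec), "interpolate")
})

test_that("segment lengths are recovered from the static window", {
  l <- c(0.30, 0.26, 0.08)
  rec <- make_static_recording(l = l, n = 200)
  expect_equal(unname(segment_lengths(rec, 5)), l, tolerance = 1e-12)
  # exactly the first 150 frames (5 s at 30 fps) enter the average: moving
  # the later frames far away must not change the estimate
  rec2 <- rec
  rec2$joints$wrist[151:200, "x"] <- rec2$joints$wrist[151:200, "x"] + 1
  expect_equal(segment_lengths(rec2, 5), segment_lengths(rec, 5))
  expect_error(segment_lengths(make_static_recording(n = 60), 5), "shorter")
  # 3 mm marker noise: mean-of-frames estimator within 1 mm over 20 seeds
  errs <- vapply(1:20, function(s) {
    max(abs(segment_lengths(make_static_recording(l = l, noise = 3e-3,
                                                  seed = s), 5) - l))
  }, numeric(1))
  expect_true(all(errs < 1e-3))
})

test_that("planar angle extraction honours the angle convention", {
  rec <- make_static_recording(n = 150)
  inp <- extract_planar_angles(rec)
  expect_lt(max(abs(inp$theta)), 1e-9)           # straight down: all zero
  expect_lt(max(abs(inp$wrist_y_disp)), 1e-12)
  # 90 degree shoulder flexion, straight elbow and wrist
  geo <- arm_geometry()
  th <- rbind(matrix(0, 10, 3), matrix(rep(c(pi / 2, 0, 0), each = 140), 140))
  fk <- forward_kinematics(th, geo)
  n <- nrow(th)
  joints <- list(shoulder = cbind(x = rep(0, n), y = rep(0, n), z = rep(0, n)),
                 elbow = cbind(x = fk$elbow[, "x"], y = fk$elbow[, "y"], z = rep(0, n)),
                 wrist = cbind(x = fk$wrist[, "x"], y = fk$wrist[, "y"], z = rep(0, n)),
                 hand = cbind(x = fk$hand[, "x"], y = fk$hand[, "y"], z = rep(0, n)))
  inp2 <- extract_planar_angles(skeleton_recording((0:(n - 1)) / 30, joints))
  expect_equal(unname(inp2$theta[n, ]), c(pi / 2, 0, 0), tolerance = 1e-9)
  # mirrored (other side) capture gives the same positive flexion angles
  joints_m <- lapply(joints, function(m) { m[, "x"] <- -m[, "x"]; m })
  inp3 <- extract_planar_angles(skeleton_recording((0:(n - 1)) / 30, joints_m))
  expect_equal(inp3$theta, inp2$theta, tolerance = 1e-9)
})

test_that("render-then-extract round trip recovers the simulated motion", {
  syn <- synth_normal_noiseless
  input <- prepare_input(syn$recording)
  onset <- which(input$time >= 5)[1]
  n_keep <- min(nrow(syn$trajectory$state), length(input$time) - onset + 1)
  th_meas <- input$theta[onset:(onset + n_keep - 1), ]
  th_true <- syn$trajectory$state[1:n_keep, 1:3]
  rms_deg <- sqrt(mean((th_meas - th_true)^2)) * 180 / pi
  expect_lt(rms_deg, 0.5)
  wy_meas <- input$wrist_y_disp[onset:(onset + n_keep - 1)] -
    input$wrist_y_disp[onset]
  wy_true <- syn$trajectory$wrist[1:n_keep, "y"] - syn$trajectory$wrist[1, "y"]
  expect_lt(sqrt(mean((wy_meas - wy_true)^2)), 2e-3)
  # measured segment lengths match the generating geometry
  expect_equal(unname(input$lengths), syn$geometry$lengths, tolerance = 1e-9)
})

test_that("dropped frames are interpolated onto the nominal grid", {
  rec <- make_static_recording(n = 60)
  fs <- 30; t30 <- (0:59) / fs
  rec$joints$wrist[, "z"] <- 0.1 * t30          # a ramp channel to check
  drop_idx <- c(13, 14, 40)
  rec_gappy <- skeleton_recording(rec$time[-drop_idx],
                                  lapply(rec$joints, function(m) m[-drop_idx, ]),
                                  fps = 30)
  expect_error(resample_recording(rec_gappy), "interpolate")
  expect_message(filled <- fill_gaps(rec_gappy), "3 dropped")
  expect_equal(length(filled$time), 60)
  expect_equal(filled$joints$wrist[, "z"], 0.1 * t30, tolerance = 1e-12)
  expect_silent(up <- resample_recording(filled))
  expect_equal(length(up$time), 120)
  # already-uniform recordings pass through untouched
  expect_identical(fill_gaps(rec), rec)
})
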