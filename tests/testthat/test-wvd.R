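# Pseudo Wigner-Ville distribution and cumulative time-frequency energy.

test_that("a pure tone is localized at its frequency", {
  fs <- 60; t <- (0:1199) / fs
  x <- cos(2 * pi * 5 * t)
  map <- wvd(x, fs)
  marg <- colSums(map$W)
  f_hat <- map$freq[which.max(marg)]
  df <- diff(map$freq[1:2])
  expect_lt(abs(f_hat - 5), df + 1e-12)
})

test_that("the distribution integrates to the signal energy", {
  fs <- 60; t <- (0:1199) / fs
  x <- cos(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 11 * t)
  map <- wvd(x, fs)
  expect_equal(cumulative_energy(map, clip = FALSE), sum(x^2) / fs,
               tolerance = 0.02)
  # and for the raw (unwindowed, non-analytic) transform as well
  map_raw <- wvd(x, fs, window = NULL, analytic = FALSE)
  expect_equal(cumulative_energy(map_raw, clip = FALSE), sum(x^2) / fs,
               tolerance = 0.02)
})

test_that("the ridge of a linear chirp tracks the instantaneous frequency", {
  fs <- 60; n <- 1200; t <- (0:(n - 1)) / fs
  f0 <- 2; f1 <- 20
  x <- cos(2 * pi * (f0 * t + (f1 - f0) / (2 * max(t)) * t^2))
  fi <- f0 + (f1 - f0) * t / max(t)      # analytic instantaneous frequency
  map <- wvd(x, fs)
  df <- diff(map$freq[1:2])
  mid <- seq(round(0.1 * n), round(0.9 * n))
  ridge <- map$freq[apply(map$W[mid, ], 1, which.max)]
  expect_lte(max(abs(ridge - fi[mid])), 2 * df + 1e-12)
})

test_that("time-shifting the signal time-shifts the distribution", {
  fs <- 60
  burst <- function(t0) {
    t <- (0:899) / fs
    exp(-((t - t0) / 0.5)^2) * cos(2 * pi * 8 * t)
  }
  m1 <- wvd(burst(5), fs)
  m2 <- wvd(burst(7), fs)
  shift <- round(2 * fs)
  idx <- 200:500
  expect_equal(m1$W[idx, ], m2$W[idx + shift, ], tolerance = 1e-6)
})

test_that("cumulative energy matches a brute-force double sum", {
  set.seed(13)
  fs <- 60
  x <- rnorm(300)
  map <- wvd(x, fs)
  W <- map$W; W[W < 0] <- 0
  t_max <- 3; f_max <- 14
  it <- which(map$time <= t_max); jf <- which(map$freq <= f_max)
  # independent iterated trapezoid by explicit loops
  tsel <- map$time[it]; fsel <- map$freq[jf]
  rowi <- numeric(length(it))
  for (a in seq_along(it)) {
    s <- 0
    for (b in seq_len(length(jf) - 1)) {
      s <- s + (fsel[b + 1] - fsel[b]) * (W[it[a], jf[b]] + W[it[a], jf[b + 1]]) / 2
    }
    rowi[a] <- s
  }
  brute <- 0
  for (a in seq_len(length(it) - 1)) {
    brute <- brute + (tsel[a + 1] - tsel[a]) * (rowi[a] + rowi[a + 1]) / 2
  }
  expect_equal(cumulative_energy(map, t_max, f_max), brute, tolerance = 1e-12)
  expect_equal(cumulative_energy(map, t_max = 0, f_max = f_max), 0)
  expect_error(cumulative_energy(map, t_max = 1e3), "outside")
})

test_that("degenerate inputs are rejected", {
  expect_error(wvd(rnorm(10), 60), "64")
  expect_error(wvd(rnorm(100), 60, window = 64L), "odd")
})
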