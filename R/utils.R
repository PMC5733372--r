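# small internal numerics helpers

# trapezoidal quadrature over a (possibly non-uniform) grid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# cumulative trapezoid, same length as x, starting at 0
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# check a time grid is uniform; returns dt
.uniform_dt <- function(time, what = "time grid", tol = 1e-8) {
  d <- diff(time)
  if (length(d) == 0L || any(d <= 0) || (max(d) - min(d)) > tol * max(d))
    stop(sprintf("%s must be strictly increasing and uniform", what), call. = FALSE)
  mean(d)
}

# analytic signal via FFT: zero out negative frequencies, double positive ones
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
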