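# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Analytic natural cubic spline: solves the tridiagonal system for the
# second derivatives directly and evaluates piecewise, independent of
# stats::splinefun.
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  if (n == 2) {
    # degenerate: a straight line
    return(y[1] + (y[2] - y[1]) / h[1] * (xout - x[1]))
  }
  # interior second derivatives from the standard tridiagonal system
  A <- matrix(0, n - 2, n - 2)
  rhs <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    r <- i - 1
    if (r > 1) A[r, r - 1] <- h[i - 1]
    A[r, r] <- 2 * (h[i - 1] + h[i])
    if (r < n - 2) A[r, r + 1] <- h[i]
    rhs[r] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  m <- c(0, solve(A, rhs), 0) # natural boundary: zero curvature at ends
  sapply(xout, function(xx) {
    i <- findInterval(xx, x, all.inside = TRUE)
    dx <- xx - x[i]
    hh <- h[i]
    a <- (x[i + 1] - xx) / hh
    b <- dx / hh
    a * y[i] + b * y[i + 1] +
      ((a^3 - a) * m[i] + (b^3 - b) * m[i + 1]) * hh^2 / 6
  })
}

# Direct transcription of the Thornthwaite formulation, kept separate from
# the package implementation.
thornthwaite_oracle <- function(temp12, latitude) {
  I <- sum(pmax(temp12, 0)^1.514) / 5^1.514
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  dim <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  J <- cumsum(dim) - dim / 2
  delta <- 0.409 * sin(2 * pi / 365 * J - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(latitude * pi / 180) * tan(delta))))
  N <- 24 / pi * ws
  ifelse(temp12 <= 0, 0,
         16 * (10 * temp12 / I)^a * (N / 12) * (dim / 30))
}

# Fixed no-noise generator settings used by several recovery tests.
noiseless_params <- function(...) {
  generator_params(delta_noise_sd = 0, pct_c_cv = 0, mass_cv = 0,
                   delta_r_sd = 0, acid_ratio_sd = 0, bg_noise_sd = c(0, 0),
                   ...)
}
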