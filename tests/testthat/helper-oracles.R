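# Independent oracles used across the suite.

# Brute-force sliding-window contrast: explicit per-pixel double loop with
# the same symmetric reflective padding contract, sample (n-1) sd.
brute_contrast <- function(frame, w = 5) {
  p <- (w - 1L) %/% 2L
  n <- nrow(frame); m <- ncol(frame)
  P <- frame[c(p:1, 1:n, n:(n - p + 1)), c(p:1, 1:m, m:(m - p + 1))]
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      win <- P[i:(i + w - 1L), j:(j + w - 1L)]
      out[i, j] <- stats::sd(win) / mean(win)
    }
  }
  out
}

# Finite-exposure speckle contrast by numerical quadrature of the field
# autocovariance: K^2 = beta * 2 \int_0^1 (1 - u) |g1(x u)|^2 du with
# g1(s) = exp(-s), x = T / tau_c. Independent of the closed form.
quad_k2 <- function(x, beta = 1) {
  beta * 2 * stats::integrate(function(u) (1 - u) * exp(-2 * x * u),
                              0, 1, rel.tol = 1e-10)$value
}

# Closed-form finite-exposure contrast curve.
closed_k2 <- function(x, beta = 1) {
  beta * (exp(-2 * x) - 1 + 2 * x) / (2 * x^2)
}

# Mean squared global spatial contrast of a movie's frames.
measured_k2 <- function(movie) mean(global_contrast(movie)^2)
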