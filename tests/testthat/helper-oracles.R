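# Closed-form oracles used across the test files.

# P(message in [x_i - eps, x_i + eps]) for a message drawn from a normal
# centred at x_j with sd nu, truncated to [0,1] by rejection.
truncnorm_accept_prob <- function(x_i, x_j, eps, nu) {
  lo <- max(0, x_i - eps)
  hi <- min(1, x_i + eps)
  z <- pnorm((1 - x_j) / nu) - pnorm((0 - x_j) / nu)
  if (hi <= lo) return(0)
  (pnorm((hi - x_j) / nu) - pnorm((lo - x_j) / nu)) / z
}

# exact mean and population s.d. of the calibrated six-interval density:
# category k has probability p[k] and is uniform on ((k-1)/6, k/6)
sixam_moments <- function(p) {
  k <- 1:6
  a <- (k - 1) / 6
  b <- k / 6
  m1 <- sum(p * (a + b) / 2)
  m2 <- sum(p * (a^2 + a * b + b^2) / 3)
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# mean of a half-normal: a sender pinned at the boundary x = 1 emits
# messages with mean 1 - nu * sqrt(2/pi)
halfnormal_boundary_mean <- function(nu) 1 - nu * sqrt(2 / pi)

# small configs used by several files
quick_config <- function(...) {
  model_config(n = 30, steps = 2000, snapshot_every = 500, ...)
}
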