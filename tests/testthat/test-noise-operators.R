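test_that("bc_pair_update follows the bounded-confidence rule", {
  expect_equal(bc_pair_update(0.5, 0.6, epsilon = 0.2, mu = 0.5), 0.55)
  expect_equal(bc_pair_update(0.1, 0.9, epsilon = 0.2, mu = 0.5), 0.1)
  # identity case for a grid of parameters
  for (x in c(0, 0.25, 1)) for (eps in c(0, 0.5)) for (mu in c(0.1, 0.5))
    expect_identical(bc_pair_update(x, x, eps, mu), x)
  # boundary comparison is non-strict
  expect_equal(bc_pair_update(0.4, 0.6, epsilon = 0.2, mu = 0.5), 0.5)
  # vectorized
  expect_equal(bc_pair_update(c(0.5, 0.1), c(0.6, 0.9), 0.2, 0.5),
               c(0.55, 0.1))
  expect_error(bc_pair_update(-0.1, 0.5, 0.2, 0.5), "x_i")
  expect_error(bc_pair_update(0.5, 1.5, 0.2, 0.5), "m_j")
  expect_error(bc_pair_update(0.5, 0.5, 0.2, 0.9), "mu")
})

test_that("ambiguous messages are truncated by resampling, never clipped", {
  expect_identical(draw_ambiguous_message(0.5, 0), 0.5)
  set.seed(1)
  m <- draw_ambiguous_message(rep(0, 1e5), 0.05)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(sum(m == 0), 0) # clipping would pile mass on the bound
  set.seed(2)
  mu_ <- draw_ambiguous_message(rep(0.3, 1e4), 0.1, "bounded_uniform")
  expect_true(all(abs(mu_ - 0.3) <= 0.1))
})

test_that("a boundary sender emits half-normal messages with the predicted mean", {
  # sender at x = 1 with Gaussian ambiguity: mean message 1 - nu*sqrt(2/pi)
  for (nu in c(0.05, 0.1, 0.2)) {
    set.seed(100 + round(1000 * nu))
    m <- draw_ambiguous_message(rep(1, 2e5), nu)
    se <- nu * sqrt(1 - 2 / pi) / sqrt(2e5)
    expect_lt(abs(mean(m) - halfnormal_boundary_mean(nu)), 4 * se + 1e-4)
    expect_true(all(m <= 1))
  }
})

test_that("selectivity acceptance matches the normal-tail law", {
  # P(accept) = 1 - Phi((gap - eps)/nu)
  cases <- expand.grid(gap = c(0, 0.1, 0.3), eps = c(0.1, 0.2),
                       nu = c(0.05, 0.1))
  set.seed(11)
  for (i in seq_len(nrow(cases))) {
    g <- cases$gap[i]; eps <- cases$eps[i]; nu <- cases$nu[i]
    acc <- accept_selectivity(rep(0.2, 1e5), rep(0.2 + g, 1e5), eps, nu)
    p <- 1 - pnorm((g - eps) / nu)
    expect_lt(abs(mean(acc) - p), 3 * sqrt(p * (1 - p) / 1e5) + 1e-4)
  }
  # nu = 0: deterministic, non-strict at the bound, no RNG consumed
  set.seed(3); before <- runif(1); set.seed(3)
  expect_true(accept_selectivity(0.3, 0.5, epsilon = 0.2, nu = 0))
  expect_identical(runif(1), before)
  expect_false(accept_selectivity(0.3, 0.51, epsilon = 0.2, nu = 0))
  # zero gap: accepted whenever the noisy bound is non-negative, >= 1/2
  set.seed(4)
  acc0 <- accept_selectivity(rep(0.5, 1e5), rep(0.5, 1e5), 0.05, 0.2)
  expect_gte(mean(acc0), 0.5)
})

test_that("ambiguity acceptance matches the truncated-normal interval law", {
  cases <- data.frame(x_i = c(0.5, 0.3, 0.9), x_j = c(0.6, 0.8, 1.0),
                      eps = c(0.2, 0.3, 0.15), nu = c(0.1, 0.2, 0.1))
  set.seed(21)
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      m <- draw_ambiguous_message(rep(x_j, 1e5), nu)
      acc <- abs(m - x_i) <= eps
      p <- truncnorm_accept_prob(x_i, x_j, eps, nu)
      expect_lt(abs(mean(acc) - p), 3 * sqrt(p * (1 - p) / 1e5) + 1e-4)
    })
  }
})

test_that("adaptation shifts are zero-mean for interior opinions and truncated at bounds", {
  expect_identical(adaptation_shift(0.55, 0), 0.55)
  set.seed(31)
  s <- adaptation_shift(rep(0.5, 2e5), 0.1)
  expect_lt(abs(mean(s) - 0.5), 4 * 0.1 / sqrt(2e5) + 1e-4)
  expect_lt(abs(sd(s) - 0.1), 2e-3)
  s1 <- adaptation_shift(rep(1, 2e5), 0.1)
  expect_true(all(s1 <= 1))
  expect_lt(abs(mean(s1) - halfnormal_boundary_mean(0.1)), 1e-3)
})

test_that("exogenous jumps hit a binomial share of agents with the right amplitude", {
  expect_identical(apply_exogenous_jumps(c(0.2, 0.8), 0), c(0.2, 0.8))
  set.seed(41)
  n <- 100; reps <- 2000; nu <- 0.1
  jumps <- 0
  for (r in seq_len(reps)) {
    x <- rep(0.5, n)
    y <- apply_exogenous_jumps(x, nu)
    jumps <- jumps + sum(y != x)
  }
  expected <- n * reps * nu
  expect_lt(abs(jumps - expected), 3 * sqrt(n * reps * nu * (1 - nu)))
  # conditioned on jumping, the jump s.d. is ~nu (interior anchor)
  set.seed(42)
  dev <- replicate(4000, {
    y <- apply_exogenous_jumps(rep(0.5, 20), 0.2)
    y[y != 0.5] - 0.5
  })
  dev <- unlist(dev)
  expect_gt(length(dev), 1000)
  expect_lt(abs(sd(dev) - 0.2), 0.01)
  expect_error(apply_exogenous_jumps(0.5, 1.2), "probability")
})
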