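#' Simulation configuration
#'
#' Collects every parameter of a single run. The defaults reproduce the
#' standard experimental protocol: `n = 100` fully connected agents,
#' maximum convergence speed `mu = 0.5`, and `steps = 1e5` time steps
#' (each step is one randomly drawn dyadic exchange, so each agent engages
#' in `2 * steps / n` = 2000 interactions on average).
#'
#' @param n number of agents (>= 2).
#' @param mu convergence speed, in (0, 0.5].
#' @param epsilon confidence bound, in \[0,1\]. Small `epsilon` = strong
#'   confirmation bias.
#' @param steps number of time steps.
#' @param noise a [noise_spec()].
#' @param init initial-condition generator: `"uniform"` (i.i.d. U\[0,1\])
#'   or `"six_americas"` (survey-calibrated, see [init_six_americas()]).
#' @param profile category proportions for the calibrated initializer
#'   (see [six_americas_profile()]); ignored for `init = "uniform"`.
#' @param regime communication regime: `"one_to_one"` dyadic exchange,
#'   `"many_to_one"` (one receiver aggregates `regime_k` senders) or
#'   `"one_to_many"` (one sender broadcasts to `regime_k` receivers).
#' @param regime_k fan-in/out for the non-dyadic regimes (2 <= k < n).
#' @param topology `"complete"` (any pair may interact) or `"small_world"`
#'   (Watts-Strogatz; dyads drawn uniformly over edges).
#' @param sw_degree,sw_rewire small-world parameters (even degree,
#'   rewiring probability).
#' @param seed integer seed; fully determines every random draw of the run.
#' @param snapshot_every recording cadence in steps (> 0); the states at
#'   step 0 and at `steps` are always recorded.
#' @return an object of class `bc_config`.
#' @export
#' @examples
#' model_config(epsilon = 0.175, noise = noise_spec("ambiguity", 0.13))
model_config <- function(n = 100, mu = 0.5, epsilon = 0.2, steps = 1e5,
                         noise = noise_spec("none"),
                         init = c("uniform", "six_americas"),
                         profile = six_americas_profile(),
                         regime = c("one_to_one", "many_to_one",
                                    "one_to_many"),
                         regime_k = 10,
                         topology = c("complete", "small_world"),
                         sw_degree = 10, sw_rewire = 0.1,
                         seed = 1L, snapshot_every = 1000) {
  init <- match.arg(init)
  regime <- match.arg(regime)
  topology <- match.arg(topology)
  cfg <- structure(list(
    n = as.integer(n), mu = as.numeric(mu), epsilon = as.numeric(epsilon),
    steps = as.integer(steps), noise = noise, init = init,
    profile = profile, regime = regime, regime_k = as.integer(regime_k),
    topology = topology, sw_degree = as.integer(sw_degree),
    sw_rewire = as.numeric(sw_rewire), seed = as.integer(seed),
    snapshot_every = as.integer(snapshot_every)
  ), class = "bc_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "bc_config"))
  fail <- function(...) stop(sprintf(...), call. = FALSE)
  if (is.na(cfg$n) || cfg$n < 2) fail("n must be an integer >= 2")
  if (is.na(cfg$mu) || cfg$mu <= 0 || cfg$mu > 0.5)
    fail("mu must lie in (0, 0.5], got %g", cfg$mu)
  if (is.na(cfg$epsilon) || cfg$epsilon < 0 || cfg$epsilon > 1)
    fail("epsilon must lie in [0,1], got %g", cfg$epsilon)
  if (is.na(cfg$steps) || cfg$steps < 0) fail("steps must be >= 0")
  if (!inherits(cfg$noise, "noise_spec"))
    fail("`noise` must be a noise_spec()")
  if (cfg$noise$level < 0) fail("noise level must be >= 0")
  if (cfg$noise$type == "exogenous" && cfg$noise$level > 1)
    fail("exogenous noise level is also a probability; must be <= 1")
  if (!cfg$regime %in% .regimes) fail("unknown regime '%s'", cfg$regime)
  if (cfg$regime != "one_to_one") {
    if (is.na(cfg$regime_k) || cfg$regime_k < 2)
      fail("regime_k must be >= 2 for regime '%s'", cfg$regime)
    if (cfg$regime_k >= cfg$n)
      fail("regime_k (%d) must be smaller than n (%d)",
           cfg$regime_k, cfg$n)
  }
  if (!cfg$topology %in% .topologies)
    fail("unknown topology '%s'", cfg$topology)
  if (cfg$topology == "small_world") {
    if (cfg$regime != "one_to_one")
      fail("small_world topology is only defined for the one_to_one regime")
    if (cfg$sw_degree < 2 || cfg$sw_degree %% 2 != 0)
      fail("sw_degree must be a positive even integer")
    if (cfg$sw_degree >= cfg$n) fail("sw_degree must be smaller than n")
    if (cfg$sw_rewire < 0 || cfg$sw_rewire > 1)
      fail("sw_rewire must lie in [0,1]")
  }
  if (cfg$init == "six_americas") validate_profile(cfg$profile)
  if (is.na(cfg$snapshot_every) || cfg$snapshot_every <= 0)
    fail("snapshot_every must be a positive integer")
  if (is.na(cfg$seed)) fail("seed must be an integer")
  invisible(cfg)
}

#' @export
print.bc_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<bc_config> n=%d mu=%g epsilon=%g steps=%d\n",
    "  noise: %s (level=%g, %s)\n",
    "  init=%s regime=%s topology=%s seed=%d snapshot_every=%d\n"),
    x$n, x$mu, x$epsilon, x$steps,
    x$noise$type, x$noise$level, x$noise$distribution,
    x$init, x$regime, x$topology, x$seed, x$snapshot_every))
  invisible(x)
}
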