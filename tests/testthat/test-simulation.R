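# raw call into the compiled kernel, bypassing run_simulation's seeding
engine_run <- function(cfg, x0, edges, steps) {
  e0 <- if (is.null(edges)) matrix(integer(0), 0, 2) else edges - 1L
  noisybc:::bc_run_cpp(
    x0, steps, cfg$mu, cfg$epsilon,
    match(cfg$noise$type, noisybc:::.noise_types) - 1L, cfg$noise$level,
    match(cfg$noise$distribution, noisybc:::.noise_dists) - 1L,
    match(cfg$regime, noisybc:::.regimes) - 1L, cfg$regime_k,
    e0, c(0L, as.integer(steps)))
}

test_that("the pure-R step reproduces the compiled engine draw-for-draw", {
  steps <- 250
  for (ty in c("none", "ambiguity", "selectivity", "adaptation",
               "exogenous"))
    for (dd in c("gaussian", "bounded_uniform"))
      for (rg in c("one_to_one", "many_to_one", "one_to_many")) {
        cfg <- model_config(n = 20, epsilon = 0.3, steps = steps,
                            noise = noise_spec(ty,
                                               if (ty == "none") 0 else 0.1,
                                               dd),
                            regime = rg, regime_k = 5, seed = 11)
        set.seed(cfg$seed)
        x0 <- noisybc:::make_initial_state(cfg)
        res <- engine_run(cfg, x0, NULL, steps)
        set.seed(cfg$seed)
        x <- noisybc:::make_initial_state(cfg)
        for (s in seq_len(steps)) x <- simulation_step(x, cfg)
        expect_identical(as.numeric(res$snapshots[2, ]), as.numeric(x),
                         info = paste(ty, dd, rg))
      }
})

test_that("the pure-R step matches the engine on a small-world graph", {
  cfg <- model_config(n = 30, epsilon = 0.3, steps = 300,
                      noise = noise_spec("ambiguity", 0.1),
                      topology = "small_world", seed = 3)
  set.seed(cfg$seed)
  x0 <- noisybc:::make_initial_state(cfg)
  edges <- make_topology(cfg)
  res <- engine_run(cfg, x0, edges, 300)
  set.seed(cfg$seed)
  x <- noisybc:::make_initial_state(cfg)
  edges2 <- make_topology(cfg)
  expect_identical(edges, edges2)
  for (s in seq_len(300)) x <- simulation_step(x, cfg, edges2)
  expect_identical(as.numeric(res$snapshots[2, ]), as.numeric(x))
  # only linked pairs ever interact: with no rewiring, a ring stays local
  ring <- model_config(n = 40, epsilon = 1, steps = 2000,
                       topology = "small_world", sw_degree = 2,
                       sw_rewire = 0, seed = 5, snapshot_every = 2000)
  r <- run_simulation(ring)
  expect_true(all(r$interactions > 0))
})

test_that("a run is bit-reproducible from its seed", {
  cfg <- model_config(n = 50, epsilon = 0.2, steps = 5000,
                      noise = noise_spec("ambiguity", 0.1), seed = 99,
                      snapshot_every = 1000)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$summary, b$summary)
  expect_identical(a$interactions, b$interactions)
})

test_that("nu = 0 reproduces the noiseless trajectory for every noise type", {
  base <- model_config(n = 40, epsilon = 0.25, steps = 4000, seed = 17,
                       snapshot_every = 500)
  ref <- run_simulation(base)
  for (ty in c("ambiguity", "selectivity", "adaptation", "exogenous")) {
    cfg <- base
    cfg$noise <- noise_spec(ty, 0)
    expect_identical(run_simulation(cfg)$snapshots, ref$snapshots,
                     info = ty)
  }
})

test_that("noiseless runs conserve the mean and never increase dispersion", {
  cfg <- model_config(n = 50, epsilon = 0.3, steps = 2e4, seed = 23,
                      snapshot_every = 100)
  r <- run_simulation(cfg)
  means <- rowMeans(r$snapshots)
  expect_lt(max(abs(means - means[1])), 1e-10)
  disp <- apply(r$snapshots, 1, dispersion)
  expect_true(all(diff(disp) <= 1e-12))
  # drift is zero up to round-off when the mean is conserved
  expect_lt(abs(drift_statistic(r)), 1e-10)
})

test_that("one dyadic step is symmetric and conserves the pair sum", {
  cfg <- model_config(n = 2, epsilon = 0.3, steps = 1, seed = 1)
  set.seed(4)
  out <- simulation_step(c(0.2, 0.4), cfg)
  expect_equal(out, c(0.3, 0.3))
  set.seed(31)
  for (rep in 1:200) {
    x <- runif(2)
    y <- simulation_step(x, cfg)
    expect_lt(abs(sum(y) - sum(x)), 1e-14)
  }
})

test_that("opinions stay inside [0,1] under every noise type and level", {
  for (ty in c("ambiguity", "selectivity", "adaptation", "exogenous"))
    for (nu in c(0.01, 0.1, 0.3))
      for (dd in c("gaussian", "bounded_uniform")) {
        cfg <- model_config(n = 50, epsilon = 0.2, steps = 2e4,
                            noise = noise_spec(ty, nu, dd),
                            seed = 1000 + round(100 * nu),
                            snapshot_every = 200)
        r <- run_simulation(cfg)
        expect_true(all(r$snapshots >= 0 & r$snapshots <= 1),
                    info = paste(ty, nu, dd))
      }
})

test_that("every agent averages 2*steps/n dyadic interactions", {
  cfg <- model_config(epsilon = 0.2, noise = noise_spec("ambiguity", 0.1),
                      seed = 8, snapshot_every = 1e5)
  r <- run_simulation(cfg)
  expect_equal(sum(r$interactions), 2L * cfg$steps)
  expect_equal(mean(r$interactions), 2 * cfg$steps / cfg$n) # = 2000
  # per-agent counts are Binomial(steps, 2/n): allow 5 s.d. for the max
  sdev <- sqrt(cfg$steps * (2 / cfg$n) * (1 - 2 / cfg$n))
  expect_true(all(abs(r$interactions - 2000) < 5 * sdev))
})

test_that("summary rows are recomputable from the stored snapshots", {
  cfg <- model_config(n = 60, epsilon = 0.15,
                      noise = noise_spec("ambiguity", 0.08),
                      steps = 3000, seed = 55, snapshot_every = 750)
  r <- run_simulation(cfg)
  expect_equal(r$snapshot_steps[1], 0)
  expect_equal(r$snapshot_steps[length(r$snapshot_steps)], cfg$steps)
  for (i in seq_along(r$snapshot_steps)) {
    re <- opinion_summary(r$snapshots[i, ], step = r$snapshot_steps[i])
    expect_equal(r$summary[i, ], re, ignore_attr = TRUE)
  }
  expect_identical(r$final, r$snapshots[nrow(r$snapshots), ])
})

test_that("configuration validation rejects out-of-range protocols", {
  expect_error(model_config(n = 1), "n must")
  expect_error(model_config(epsilon = 1.5), "epsilon")
  expect_error(model_config(mu = 0.7), "mu")
  expect_error(model_config(snapshot_every = 0), "snapshot_every")
  expect_error(model_config(noise = noise_spec("exogenous", 1.5)),
               "probability")
  expect_error(model_config(regime = "many_to_one", regime_k = 150),
               "regime_k")
  expect_error(model_config(topology = "small_world",
                            regime = "many_to_one"), "one_to_one")
})
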