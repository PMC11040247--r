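noise_code <- function(type) match(type, .noise_types) - 1L
dist_code  <- function(d) match(d, .noise_dists) - 1L
regime_code <- function(r) match(r, .regimes) - 1L

#' Interaction topology for a configuration
#'
#' For `"complete"` topology any unordered pair of distinct agents may be
#' drawn; for `"small_world"` a Watts-Strogatz graph is generated (using
#' the current RNG stream) and dyads are drawn uniformly over its edges.
#'
#' @param config a [model_config()].
#' @return a 2-column integer edge matrix (1-based agent ids), or `NULL`
#'   for the complete topology.
#' @export
make_topology <- function(config) {
  if (config$topology == "complete") return(NULL)
  g <- igraph::sample_smallworld(dim = 1, size = config$n,
                                 nei = config$sw_degree %/% 2,
                                 p = config$sw_rewire)
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  el
}

record_schedule <- function(steps, snapshot_every) {
  unique(c(0L, seq.int(0L, steps, by = snapshot_every), steps))
}

#' Run a full seeded simulation
#'
#' Seeds the RNG, draws the initial opinions (and the interaction graph if
#' the topology is small-world), then advances the configured number of
#' steps in the compiled stepping kernel. Identical configurations
#' (including the seed) give bit-identical results.
#'
#' @param config a [model_config()].
#' @return an object of class `bc_sim`: a list with
#'   \describe{
#'     \item{snapshots}{matrix (one row per recorded step, one column per
#'       agent) of opinions; step 0 and the final step are always present;}
#'     \item{snapshot_steps}{the recorded step numbers;}
#'     \item{summary}{per-snapshot data.frame of step, mean, dispersion,
#'       kurtosis and cluster count;}
#'     \item{final}{the opinion vector at the last step;}
#'     \item{interactions}{per-agent count of interaction participations;}
#'     \item{config}{the configuration echo.}
#'   }
#' @export
#' @examples
#' res <- run_simulation(model_config(epsilon = 0.3, steps = 2e4, seed = 7))
#' tail(res$summary, 1)
run_simulation <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  x0 <- make_initial_state(config)
  edges <- make_topology(config)
  edges0 <- if (is.null(edges))
    matrix(integer(0), 0, 2) else edges - 1L
  rec <- record_schedule(config$steps, config$snapshot_every)
  out <- bc_run_cpp(x0, config$steps, config$mu, config$epsilon,
                    noise_code(config$noise$type), config$noise$level,
                    dist_code(config$noise$distribution),
                    regime_code(config$regime), config$regime_k,
                    edges0, rec)
  snaps <- out$snapshots
  rownames(snaps) <- rec
  summary <- do.call(rbind, lapply(seq_along(rec), function(i)
    opinion_summary(snaps[i, ], step = rec[i])))
  structure(list(snapshots = snaps, snapshot_steps = rec,
                 summary = summary, final = snaps[nrow(snaps), ],
                 interactions = out$interactions,
                 config = config),
            class = "bc_sim")
}

#' @export
print.bc_sim <- function(x, ...) {
  fin <- x$summary[nrow(x$summary), ]
  cat(sprintf(paste0(
    "<bc_sim> n=%d steps=%d noise=%s(%g) epsilon=%g seed=%d\n",
    "  final: mean=%.4f dispersion=%.4f clusters=%d\n"),
    x$config$n, x$config$steps, x$config$noise$type,
    x$config$noise$level, x$config$epsilon, x$config$seed,
    fin$mean, fin$dispersion, fin$n_clusters))
  invisible(x)
}

# scalar truncated draw matching the C++ trunc_add loop draw-for-draw
step_trunc_add1 <- function(anchor, nu, distribution) {
  repeat {
    v <- anchor + draw_deviation(1L, nu, distribution)
    if (v >= 0 && v <= 1) return(v)
  }
}

# one receiver update in a dyad; mirrors the compiled dyad_update exactly
step_dyad_update <- function(xr, xs, mu, eps, type, nu, dist) {
  switch(type,
    ambiguity = {
      msg <- if (nu > 0) step_trunc_add1(xs, nu, dist) else xs
      if (abs(msg - xr) <= eps) xr + mu * (msg - xr) else xr
    },
    selectivity = {
      thr <- eps + if (nu > 0) draw_deviation(1L, nu, dist) else 0
      if (abs(xs - xr) <= thr) xr + mu * (xs - xr) else xr
    },
    adaptation = {
      if (abs(xs - xr) <= eps) {
        base <- xr + mu * (xs - xr)
        if (nu > 0) step_trunc_add1(base, nu, dist) else base
      } else xr
    },
    { # none / exogenous
      if (abs(xs - xr) <= eps) xr + mu * (xs - xr) else xr
    })
}

# partial Fisher-Yates: k distinct 1-based indices from the pool `pool`
step_sample_k <- function(pool, k) {
  nn <- length(pool)
  for (l in seq_len(k)) {
    r <- l + floor(runif(1) * (nn - l + 1))
    tmp <- pool[l]; pool[l] <- pool[r]; pool[r] <- tmp
  }
  pool[seq_len(k)]
}

#' Advance the model by one time step (reference implementation)
#'
#' Pure-R implementation of a single scheduler step, consuming the RNG
#' stream in exactly the same order as the compiled engine used by
#' [run_simulation()]; iterating it under the same seed reproduces a
#' compiled run bit-for-bit (this equivalence is part of the test suite).
#' One step is: draw the dyad (or the regime's sender/receiver set),
#' update from pre-step opinions with per-direction independent noise,
#' then apply exogenous jumps if that noise type is active.
#'
#' @param state opinion vector.
#' @param config a [model_config()] (its `seed` and `snapshot_every` are
#'   ignored here; seed the stream yourself with [set.seed()]).
#' @param edges edge matrix from [make_topology()] for small-world runs;
#'   `NULL` for the complete topology.
#' @return the new opinion vector.
#' @export
simulation_step <- function(state, config, edges = NULL) {
  n <- length(state)
  if (n < 2) stop("need at least two agents", call. = FALSE)
  type <- config$noise$type
  nu <- config$noise$level
  dist <- config$noise$distribution
  eps <- config$epsilon
  mu <- config$mu
  if (config$topology == "small_world" && is.null(edges))
    stop("small_world topology needs the `edges` matrix", call. = FALSE)

  if (config$regime == "one_to_one") {
    if (!is.null(edges)) {
      e <- 1L + floor(runif(1) * nrow(edges))
      i <- edges[e, 1]; j <- edges[e, 2]
    } else {
      i <- 1L + floor(runif(1) * n)
      repeat {
        j <- 1L + floor(runif(1) * n)
        if (j != i) break
      }
    }
    ni <- step_dyad_update(state[i], state[j], mu, eps, type, nu, dist)
    nj <- step_dyad_update(state[j], state[i], mu, eps, type, nu, dist)
    state[i] <- ni
    state[j] <- nj
  } else if (config$regime == "many_to_one") {
    r <- 1L + floor(runif(1) * n)
    senders <- step_sample_k((1:n)[-r], config$regime_k)
    xr <- state[r]
    acc <- numeric(0)
    for (s in senders) {
      xs <- state[s]
      if (type == "ambiguity") {
        msg <- if (nu > 0) step_trunc_add1(xs, nu, dist) else xs
        if (abs(msg - xr) <= eps) acc <- c(acc, msg)
      } else if (type == "selectivity") {
        thr <- eps + if (nu > 0) draw_deviation(1L, nu, dist) else 0
        if (abs(xs - xr) <= thr) acc <- c(acc, xs)
      } else {
        if (abs(xs - xr) <= eps) acc <- c(acc, xs)
      }
    }
    if (length(acc)) {
      base <- xr + mu * (sum(acc) / length(acc) - xr)
      if (type == "adaptation" && nu > 0)
        base <- step_trunc_add1(base, nu, dist)
      state[r] <- base
    }
  } else { # one_to_many
    s <- 1L + floor(runif(1) * n)
    receivers <- step_sample_k((1:n)[-s], config$regime_k)
    xs <- state[s]
    msg <- if (type == "ambiguity" && nu > 0)
      step_trunc_add1(xs, nu, dist) else xs
    for (r in receivers) {
      xr <- state[r]
      if (type == "ambiguity") {
        if (abs(msg - xr) <= eps) state[r] <- xr + mu * (msg - xr)
      } else if (type == "selectivity") {
        thr <- eps + if (nu > 0) draw_deviation(1L, nu, dist) else 0
        if (abs(xs - xr) <= thr) state[r] <- xr + mu * (xs - xr)
      } else if (type == "adaptation") {
        if (abs(xs - xr) <= eps) {
          base <- xr + mu * (xs - xr)
          if (nu > 0) base <- step_trunc_add1(base, nu, dist)
          state[r] <- base
        }
      } else {
        if (abs(xs - xr) <= eps) state[r] <- xr + mu * (xs - xr)
      }
    }
  }

  if (type == "exogenous" && nu > 0)
    state <- apply_exogenous_jumps(state, nu, dist)
  state
}
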