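#' Run a seeded ensemble of independent simulations
#'
#' Runs `replicates` independent simulations whose seeds are derived from
#' `seed` by the counter-based [derive_seed()], so the ensemble is
#' reproducible and independent of execution order. Only the initial and
#' final snapshots are recorded per replicate.
#'
#' @param config a [model_config()]; its `seed` is used as the master seed
#'   unless `seed` is given.
#' @param replicates number of replicates (>= 1).
#' @param seed master seed for the ensemble.
#' @return an object of class `bc_ensemble`: list with `replicates` (one
#'   row per run: seed, final mean, dispersion, kurtosis, cluster count,
#'   PEA flag, drift) and `summary` (one row of ensemble aggregates:
#'   mean/s.d. of final dispersion, mean final mean, PEA frequency,
#'   mean drift, replicate count).
#' @export
run_ensemble <- function(config, replicates, seed = config$seed) {
  validate_config(config)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  cfg <- config
  cfg$snapshot_every <- max(cfg$steps, 1L) # record only step 0 and final
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg$seed <- derive_seed(seed, r)
    sim <- run_simulation(cfg)
    fin <- sim$final
    rows[[r]] <- data.frame(
      replicate = r, seed = cfg$seed,
      final_mean = mean(fin), final_dispersion = dispersion(fin),
      final_kurtosis = if (dispersion(fin) > 0) excess_kurtosis(fin)
                       else NA_real_,
      n_clusters = count_clusters(fin),
      pea = is_pea(fin), drift = drift_statistic(sim))
  }
  reps <- do.call(rbind, rows)
  summary <- data.frame(
    noise_type = config$noise$type, epsilon = config$epsilon,
    nu = config$noise$level, replicates = replicates,
    mean_final_dispersion = mean(reps$final_dispersion),
    sd_final_dispersion = sd(reps$final_dispersion),
    mean_final_mean = mean(reps$final_mean),
    pea_frequency = mean(reps$pea),
    mean_drift = mean(reps$drift))
  structure(list(replicates = reps, summary = summary,
                 config = config, seed = seed),
            class = "bc_ensemble")
}

#' @export
print.bc_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<bc_ensemble> %d replicates, noise=%s(%g), epsilon=%g\n",
    "  mean final dispersion=%.4f  PEA frequency=%.3f\n"),
    s$replicates, s$noise_type, s$nu, s$epsilon,
    s$mean_final_dispersion, s$pea_frequency))
  invisible(x)
}

#' Specify an (epsilon, nu) ensemble grid
#'
#' @param epsilon confidence-bound values.
#' @param nu noise-level values.
#' @param noise_types one or more noise types to sweep.
#' @param replicates replicates per grid cell (>= 1).
#' @param base base [model_config()] supplying all other parameters
#'   (n, mu, steps, regime, topology, seed, initializer...).
#' @param distribution deviation family for every cell.
#' @return an object of class `bc_grid`.
#' @export
grid_spec <- function(epsilon, nu,
                      noise_types = "ambiguity",
                      replicates = 100,
                      base = model_config(),
                      distribution = c("gaussian", "bounded_uniform")) {
  distribution <- match.arg(distribution)
  if (length(epsilon) < 1 || length(nu) < 1 || length(noise_types) < 1)
    stop("grids must be non-empty", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (!all(noise_types %in% .noise_types))
    stop("unknown noise type(s): ",
         paste(setdiff(noise_types, .noise_types), collapse = ", "),
         call. = FALSE)
  structure(list(epsilon = as.numeric(epsilon), nu = as.numeric(nu),
                 noise_types = noise_types,
                 replicates = as.integer(replicates), base = base,
                 distribution = distribution),
            class = "bc_grid")
}

# canonical cell table: sorted so per-cell seeds do not depend on the
# order in which values were listed or cells are executed
grid_cells <- function(grid) {
  cells <- expand.grid(noise_type = sort(unique(grid$noise_types)),
                       epsilon = sort(unique(grid$epsilon)),
                       nu = sort(unique(grid$nu)),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$noise_type, cells$epsilon, cells$nu), ]
  cells$cell <- seq_len(nrow(cells))
  rownames(cells) <- NULL
  cells
}

#' Sweep an (epsilon, nu) grid of ensembles
#'
#' Runs [run_ensemble()] for every (noise type, epsilon, nu) cell of the
#' grid. Per-cell master seeds are derived from the base config's seed and
#' the cell's position in the canonical (sorted) cell order.
#'
#' @param grid a [grid_spec()].
#' @return an object of class `bc_sweep`: list with `cells` (tidy
#'   data.frame keyed by noise_type, epsilon, nu with the ensemble
#'   aggregates) and the grid echo.
#' @export
sweep_grid <- function(grid) {
  stopifnot(inherits(grid, "bc_grid"))
  cells <- grid_cells(grid)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- grid$base
    cfg$epsilon <- cells$epsilon[i]
    cfg$noise <- noise_spec(cells$noise_type[i], cells$nu[i],
                            grid$distribution)
    validate_config(cfg)
    ens <- run_ensemble(cfg, grid$replicates,
                        seed = derive_seed(grid$base$seed, cells$cell[i]))
    out[[i]] <- ens$summary
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  structure(list(cells = tab, grid = grid), class = "bc_sweep")
}

#' @export
print.bc_sweep <- function(x, ...) {
  cat(sprintf("<bc_sweep> %d cells x %d replicates\n",
              nrow(x$cells), x$grid$replicates))
  print(x$cells)
  invisible(x)
}

#' PEA frequency over a grid with calibrated initial opinions
#'
#' Convenience wrapper around [sweep_grid()] that enforces the
#' survey-calibrated initializer; the `pea_frequency` column of the
#' result is the fraction of replicates whose final state satisfies
#' [is_pea()].
#'
#' @param grid a [grid_spec()] whose base config uses
#'   `init = "six_americas"`.
#' @return a `bc_sweep`.
#' @export
pea_frequency <- function(grid) {
  stopifnot(inherits(grid, "bc_grid"))
  if (grid$base$init != "six_americas")
    stop("pea_frequency requires the six-Americas calibrated initializer ",
         "(set init = 'six_americas' in the base config)", call. = FALSE)
  sweep_grid(grid)
}

# upward crossing of `threshold` in y over ascending x, linearly
# interpolated between the bracketing grid points. The agreement window is
# interior in the noise level: at very low noise the fragmented clusters of
# the noiseless model survive (dispersion above threshold), so the breaking
# transition is the first crossing *after* the dispersion has entered the
# agreement region (y <= threshold).
interp_crossing <- function(x, y, threshold) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  below <- which(y <= threshold)
  if (!length(below)) return(NA_real_)
  start <- below[1]
  k <- which(y > threshold & seq_along(y) > start)[1]
  if (is.na(k)) return(NA_real_)
  x[k - 1] + (threshold - y[k - 1]) * (x[k] - x[k - 1]) / (y[k] - y[k - 1])
}

#' Estimate the critical noise level where agreement breaks
#'
#' For adaptation (and exogenous) noise, increasing the noise level beyond
#' a threshold abruptly breaks agreement; for adaptation noise that
#' transition occurs near `nu = 0.25 * epsilon`. This estimator sweeps an
#' ascending `nu` grid, computes the ensemble mean final dispersion per
#' level, and locates the agreement-breaking transition: the first upward
#' crossing of the dispersion threshold after the dispersion has entered
#' the agreement region (the window of noise-induced agreement is interior
#' in `nu` -- at very low noise the fragmented clusters of the noiseless
#' model survive), linearly interpolated between the bracketing points.
#'
#' @param epsilon confidence bound.
#' @param noise_type the noise type to sweep.
#' @param nu_grid ascending noise levels straddling the transition.
#' @param replicates replicates per level.
#' @param base base [model_config()].
#' @param threshold dispersion level separating agreement from
#'   disagreement (0.1).
#' @return list: `nu_critical`, `ratio` (= nu_critical / epsilon) and the
#'   per-level `table`. Errors if the grid contains no crossing.
#' @export
estimate_critical_noise <- function(epsilon, noise_type, nu_grid,
                                    replicates = 100,
                                    base = model_config(),
                                    threshold = 0.1) {
  nu_grid <- as.numeric(nu_grid)
  if (is.unsorted(nu_grid, strictly = TRUE))
    stop("nu_grid must be strictly ascending", call. = FALSE)
  grid <- grid_spec(epsilon, nu_grid, noise_type,
                    replicates = replicates, base = base)
  sw <- sweep_grid(grid)
  tab <- sw$cells[order(sw$cells$nu), ]
  nu_c <- interp_crossing(tab$nu, tab$mean_final_dispersion, threshold)
  if (is.na(nu_c))
    stop("no agreement-breaking crossing of dispersion ", threshold,
         " inside nu_grid; widen the grid", call. = FALSE)
  list(nu_critical = nu_c, ratio = nu_c / epsilon, table = tab)
}

#' Net drift of the mean opinion toward an edge
#'
#' Compares how far the population mean sits from the centre of the
#' opinion space at the final versus the initial snapshot:
#' `|mean(final) - 0.5| - |mean(initial) - 0.5|`. Positive values mean
#' the society drifted toward an edge of the opinion space; noiseless
#' runs conserve the mean, giving zero up to round-off.
#'
#' @param result a `bc_sim` from [run_simulation()].
#' @return scalar drift statistic.
#' @export
drift_statistic <- function(result) {
  stopifnot(inherits(result, "bc_sim"))
  snaps <- result$snapshots
  if (nrow(snaps) < 2) stop("need at least two snapshots", call. = FALSE)
  abs(mean(snaps[nrow(snaps), ]) - 0.5) - abs(mean(snaps[1, ]) - 0.5)
}
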