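#' Derive a replicate seed from a master seed
#'
#' Counter-based derivation: an injective affine map modulo the Mersenne
#' prime 2^31 - 1, so distinct replicate indices under one master seed
#' always get distinct seeds, the same (master, index) pair always gets
#' the same seed, and derivation is independent of the order in which
#' replicates are generated.
#'
#' @param master integer master seed.
#' @param index replicate counter (>= 0).
#' @return integer seed in \[0, 2^31 - 2\].
#' @export
#' @examples
#' derive_seed(42, 0:4)
derive_seed <- function(master, index) {
  if (any(index < 0)) stop("index must be >= 0", call. = FALSE)
  p <- 2147483647
  s <- ((as.numeric(master) %% p) * 69621 + (as.numeric(index) + 1) *
          476211) %% p
  as.integer(s)
}

config_to_list <- function(cfg) {
  list(n = cfg$n, mu = cfg$mu, epsilon = cfg$epsilon, steps = cfg$steps,
       noise = list(type = cfg$noise$type, level = cfg$noise$level,
                    distribution = cfg$noise$distribution),
       init = cfg$init, profile = as.list(cfg$profile),
       regime = cfg$regime, regime_k = cfg$regime_k,
       topology = cfg$topology, sw_degree = cfg$sw_degree,
       sw_rewire = cfg$sw_rewire, seed = cfg$seed,
       snapshot_every = cfg$snapshot_every)
}

.model_keys <- c("n", "mu", "epsilon", "steps", "noise", "init", "profile",
                 "regime", "regime_k", "topology", "sw_degree", "sw_rewire",
                 "seed", "snapshot_every")
.noise_keys <- c("type", "level", "distribution")
.grid_keys  <- c("epsilon_values", "nu_values", "noise_types", "replicates",
                 "distribution", "base")

#' Load and validate a configuration file
#'
#' Reads a JSON configuration and returns either a validated
#' [model_config()] (plain run) or a [grid_spec()] (when the file has any
#' of the grid keys `epsilon_values`, `nu_values`, `noise_types`,
#' `replicates`; other parameters then live under `base`). Unknown keys
#' are rejected; an empty object `{}` yields the default protocol
#' (n = 100, mu = 0.5, steps = 1e5).
#'
#' @param path path to a JSON file.
#' @return a `bc_config` or `bc_grid`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  if (any(names(raw) %in% .grid_keys)) {
    unknown <- setdiff(names(raw), .grid_keys)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    base <- if (is.null(raw$base)) model_config()
            else parse_model_config(raw$base)
    grid_spec(
      epsilon = if (is.null(raw$epsilon_values)) base$epsilon
                else raw$epsilon_values,
      nu = if (is.null(raw$nu_values)) base$noise$level else raw$nu_values,
      noise_types = if (is.null(raw$noise_types)) base$noise$type
                    else raw$noise_types,
      replicates = if (is.null(raw$replicates)) 100 else raw$replicates,
      base = base,
      distribution = if (is.null(raw$distribution)) "gaussian"
                     else raw$distribution)
  } else {
    parse_model_config(raw)
  }
}

parse_model_config <- function(raw) {
  unknown <- setdiff(names(raw), .model_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- raw[setdiff(names(raw), c("noise", "profile"))]
  if (!is.null(raw$noise)) {
    nz <- raw$noise
    unknown <- setdiff(names(nz), .noise_keys)
    if (length(unknown))
      stop("unknown noise key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    args$noise <- noise_spec(
      type = if (is.null(nz$type)) "none" else nz$type,
      level = if (is.null(nz$level)) 0 else nz$level,
      distribution = if (is.null(nz$distribution)) "gaussian"
                     else nz$distribution)
  }
  if (!is.null(raw$profile)) {
    pr <- unlist(raw$profile)
    if (!setequal(names(pr), .sixam_levels))
      stop("profile must name all six categories", call. = FALSE)
    args$profile <- pr[.sixam_levels]
  }
  do.call(model_config, args)
}

#' Serialize a configuration to JSON
#'
#' Round-trips with [load_config()]: loading the written file returns an
#' identical configuration.
#'
#' @param config a `bc_config` or `bc_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- if (inherits(config, "bc_grid")) {
    list(epsilon_values = config$epsilon, nu_values = config$nu,
         noise_types = config$noise_types,
         replicates = config$replicates,
         distribution = config$distribution,
         base = config_to_list(config$base))
  } else {
    config_to_list(config)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write simulation or ensemble results to disk
#'
#' Writes CSV tables plus a JSON manifest (config echo, seed, package
#' version, timestamp and output file list). The manifest is written
#' last, so its presence marks a complete result set; re-running with the
#' manifest's config and seed reproduces the CSVs byte-for-byte.
#'
#' For a single run (`bc_sim`): `snapshots.csv` in long format
#' (step, agent_id, opinion) and `summary.csv` (step, mean, dispersion,
#' kurtosis, n_clusters). For an ensemble (`bc_ensemble`):
#' `replicates.csv` and `summary.csv`. For a sweep (`bc_sweep`):
#' `cells.csv`.
#'
#' @param x a `bc_sim`, `bc_ensemble` or `bc_sweep`.
#' @param out_dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_results <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files[[name]] <<- path
  }
  if (inherits(x, "bc_sim")) {
    long <- data.frame(
      step = rep(x$snapshot_steps, each = x$config$n),
      agent_id = rep(seq_len(x$config$n), times = length(x$snapshot_steps)),
      opinion = as.vector(t(x$snapshots)))
    put(long, "snapshots.csv")
    put(x$summary, "summary.csv")
    manifest <- list(kind = "simulation", config = config_to_list(x$config),
                     seed = x$config$seed)
  } else if (inherits(x, "bc_ensemble")) {
    put(x$replicates, "replicates.csv")
    put(x$summary, "summary.csv")
    manifest <- list(kind = "ensemble", config = config_to_list(x$config),
                     seed = x$seed,
                     replicate_seeds = x$replicates$seed)
  } else if (inherits(x, "bc_sweep")) {
    put(x$cells, "cells.csv")
    manifest <- list(kind = "sweep",
                     grid = list(epsilon_values = x$grid$epsilon,
                                 nu_values = x$grid$nu,
                                 noise_types = x$grid$noise_types,
                                 replicates = x$grid$replicates,
                                 distribution = x$grid$distribution,
                                 base = config_to_list(x$grid$base)),
                     seed = x$grid$base$seed)
  } else {
    stop("write_results: unsupported object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  manifest$package_version <- as.character(packageVersion("noisybc"))
  manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$files <- as.list(files)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files[["manifest.json"]] <- manifest_path
  invisible(files)
}

#' Phase-diagram heatmap of a sweep
#'
#' Tile plot of a sweep metric over the (nu, epsilon) plane, faceted by
#' noise type (requires ggplot2).
#'
#' @param sweep a `bc_sweep`.
#' @param metric column of `sweep$cells` to map to fill.
#' @return a ggplot object.
#' @export
plot_phase_diagram <- function(sweep,
                               metric = c("mean_final_dispersion",
                                          "pea_frequency")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_phase_diagram requires ggplot2", call. = FALSE)
  df <- sweep$cells
  df$nu_f <- factor(df$nu)
  df$eps_f <- factor(df$epsilon)
  df$value <- df[[metric]]
  ggplot2::ggplot(df, ggplot2::aes(x = nu_f, y = eps_f, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~noise_type) +
    ggplot2::labs(x = "noise level ν", y = "confidence bound ε",
                  fill = metric) +
    ggplot2::theme_minimal()
}
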