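#' Simulation configuration for confidence-belt construction
#'
#' Bundles the tunable settings of the grid-inversion procedure: the total
#' simulation budget, the bounds and resolution of the cells-per-well grid,
#' the nominal coverage of the intervals, the step of the loss-probability
#' grid, and the RNG seed.
#'
#' The defaults reproduce the published procedure: 10^6 simulated platings
#' spread over a log-spaced grid from 0.001 to 10 cells per well, 90%
#' equal-tailed intervals.
#'
#' @param n_sims Total number of simulated platings, divided equally across
#'   grid points. Default `1e6`.
#' @param lambda_grid_min,lambda_grid_max Bounds of the cells-per-well grid,
#'   in cells per well. Defaults 0.001 and 10.
#' @param lambda_grid_points Number of log-spaced grid points. Default 200.
#' @param ci_level Nominal two-sided coverage of intervals. Default 0.90.
#' @param q_grid_step Step of the loss-probability grid on \[0, 1\].
#'   Default 0.005.
#' @param seed Optional integer seed. When non-`NULL`, it is applied at the
#'   start of every simulation-based routine that receives this config, so a
#'   run is fully reproducible from its echoed configuration.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_sims = 1e4, seed = 1)
#' cfg
#' @export
sim_config <- function(n_sims = 1e6,
                       lambda_grid_min = 0.001,
                       lambda_grid_max = 10,
                       lambda_grid_points = 200L,
                       ci_level = 0.90,
                       q_grid_step = 0.005,
                       seed = NULL) {
  stopifnot(
    is.numeric(n_sims), length(n_sims) == 1L, n_sims >= 1,
    is.numeric(lambda_grid_min), lambda_grid_min > 0,
    is.numeric(lambda_grid_max), lambda_grid_max > lambda_grid_min,
    is.numeric(lambda_grid_points), lambda_grid_points >= 2,
    is.numeric(ci_level), ci_level > 0, ci_level < 1,
    is.numeric(q_grid_step), q_grid_step > 0, q_grid_step <= 0.5
  )
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    seed <- as.integer(seed)
  }
  structure(
    list(
      n_sims = as.numeric(n_sims),
      lambda_grid_min = as.numeric(lambda_grid_min),
      lambda_grid_max = as.numeric(lambda_grid_max),
      lambda_grid_points = as.integer(lambda_grid_points),
      ci_level = as.numeric(ci_level),
      q_grid_step = as.numeric(q_grid_step),
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  n_sims:       %g\n", x$n_sims))
  cat(sprintf("  lambda grid:  [%g, %g], %d log-spaced points\n",
              x$lambda_grid_min, x$lambda_grid_max, x$lambda_grid_points))
  cat(sprintf("  ci_level:     %g\n", x$ci_level))
  cat(sprintf("  q_grid_step:  %g\n", x$q_grid_step))
  cat(sprintf("  seed:         %s\n", if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Coerce a plain list (e.g. from a config file) to a `sim_config`
#'
#' Unknown keys are rejected so that typos in configuration files fail loudly.
#'
#' @param x A named list with any subset of the [sim_config()] arguments.
#' @return A `sim_config` object.
#' @export
as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  stopifnot(is.list(x))
  known <- names(formals(sim_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(sim_config, x)
}

# Apply the config seed (if any) to the global RNG.
maybe_set_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  invisible(NULL)
}

# Log-spaced cells-per-well grid implied by a config.
lambda_grid <- function(config) {
  exp(seq(log(config$lambda_grid_min), log(config$lambda_grid_max),
          length.out = config$lambda_grid_points))
}

# Simulations per grid point given a total budget and grid size.
sims_per_point <- function(config, n_points) {
  n_per <- max(1L, floor(config$n_sims / n_points))
  if (n_per < 100L) {
    warning(sprintf(
      "simulation budget is only %d platings per grid point (< 100); intervals will be noisy",
      n_per))
  }
  n_per
}
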