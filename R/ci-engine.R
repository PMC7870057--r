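#' Simulate positive-well counts of a limiting-dilution plating
#'
#' Draws positive-well counts \eqn{k \sim Binomial(W, 1 - e^{-\lambda})}
#' from the global RNG (seed it, or pass a seeded [sim_config()] to the
#' higher-level routines, for reproducibility).
#'
#' @param lambda Mean cells per well.
#' @param wells_total Wells on the plate.
#' @param n Number of simulated plates.
#' @return Integer vector of length `n`.
#' @export
simulate_plating <- function(lambda, wells_total, n = 1) {
  stopifnot(wells_total >= 1, n >= 1)
  stats::rbinom(n, wells_total, p_positive(lambda))
}

# Widening-only monotonisation of belt edges: removes Monte-Carlo ripple
# while guaranteeing an interval (never a union) on inversion, and never
# shrinking the raw bands. `lo` becomes the running suffix-minimum, `hi`
# the running prefix-maximum; both are then non-decreasing.
monotonise_bands <- function(lo, hi) {
  lo <- rev(cummin(rev(lo)))
  hi <- cummax(hi)
  list(lo = lo, hi = pmax(hi, lo))
}

#' Build simulated quantile bands of positive-well counts across a grid
#'
#' For each cells-per-well value on the log-spaced grid of `config`,
#' simulates platings of a `wells_total`-well plate and records the
#' equal-tailed central interval of the positive-well count at
#' `config$ci_level`. Band edges are monotonised in \eqn{\lambda}
#' (widening-only) to remove Monte-Carlo ripple. This is the confidence
#' belt that [invert_ci()] inverts on an observed count.
#'
#' @param wells_total Wells per plate (e.g. 96).
#' @param config A [sim_config()]. The total budget `n_sims` is divided
#'   equally across grid points; fewer than 100 platings per point raises
#'   a warning.
#' @return A `data.frame` with columns `lambda`, `k_lo`, `k_hi`,
#'   `n_sims_at_point`.
#' @export
build_quantile_bands <- function(wells_total, config = sim_config()) {
  stopifnot(wells_total >= 1)
  maybe_set_seed(config)
  grid <- lambda_grid(config)
  n_per <- sims_per_point(config, length(grid))
  alpha <- (1 - config$ci_level) / 2
  probs <- c(alpha, 1 - alpha)
  lo <- hi <- numeric(length(grid))
  for (j in seq_along(grid)) {
    k <- simulate_plating(grid[j], wells_total, n_per)
    qs <- stats::quantile(k, probs, type = 1, names = FALSE)
    lo[j] <- qs[1]
    hi[j] <- qs[2]
  }
  bands <- monotonise_bands(lo, hi)
  data.frame(lambda = grid, k_lo = bands$lo, k_hi = bands$hi,
             n_sims_at_point = n_per)
}

#' Invert a confidence belt on an observed positive-well count
#'
#' Returns the interval of grid cells-per-well values whose simulated band
#' contains the observed count — the grid-inversion confidence interval for
#' \eqn{\lambda}.
#'
#' @param observed_k Observed positive wells.
#' @param bands Output of [build_quantile_bands()].
#' @return Numeric vector `c(lower, upper)` with attributes:
#'   `one_sided` (`TRUE` when `observed_k = 0`, whose lower endpoint is
#'   reported as 0), `saturated` (`TRUE` when the interval runs into the top
#'   of the grid, so the upper endpoint is a grid artifact), and `empty`
#'   (`TRUE`, with an `NA` interval and a warning, if no band contains the
#'   count).
#' @export
invert_ci <- function(observed_k, bands) {
  stopifnot(is.data.frame(bands),
            all(c("lambda", "k_lo", "k_hi") %in% names(bands)),
            observed_k >= 0)
  acc <- which(bands$k_lo <= observed_k & observed_k <= bands$k_hi)
  if (!length(acc)) {
    warning("observed count lies outside every simulated band; ",
            "empty confidence set (widen the grid or budget)")
    return(structure(c(NA_real_, NA_real_),
                     one_sided = FALSE, saturated = FALSE, empty = TRUE))
  }
  lower <- bands$lambda[min(acc)]
  upper <- bands$lambda[max(acc)]
  one_sided <- FALSE
  if (observed_k == 0 && min(acc) == 1L) {
    lower <- 0
    one_sided <- TRUE
  }
  saturated <- max(acc) == nrow(bands)
  structure(c(lower, upper),
            one_sided = one_sided, saturated = saturated, empty = FALSE)
}

#' Confidence belt for clone numbers under a multi-plate design
#'
#' Generalises [build_quantile_bands()] to a whole transfection plated at
#' several fractions. For each clone number `N` on a log-spaced grid, all
#' plates are simulated jointly (plate i at \eqn{\lambda_i = N f_i / W_i})
#' and the equal-tailed band of the combined statistic
#' \eqn{T = \sum_i k_i} (the total positive-well count across plates) is
#' recorded. The total count keeps the belt one-dimensional and its
#' expectation gradient in `N` matches the likelihood score weights
#' (\eqn{f_i e^{-\lambda_i}}), so inverting it is locally equivalent to
#' likelihood inversion and the resulting interval brackets the joint MLE.
#' The `N` grid spans `lambda_grid_min * min(W/f)` to
#' `lambda_grid_max * max(W/f)`.
#'
#' @param design A `data.frame` with columns `wells_total` and
#'   `fraction_plated` (one row per plate).
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `N`, `t_lo`, `t_hi`,
#'   `n_sims_at_point`.
#' @export
build_clone_bands <- function(design, config = sim_config()) {
  design <- as_plate_design(design)
  maybe_set_seed(config)
  n_lo <- config$lambda_grid_min * min(design$wells_total / design$fraction_plated)
  n_hi <- config$lambda_grid_max * max(design$wells_total / design$fraction_plated)
  grid <- exp(seq(log(n_lo), log(n_hi), length.out = config$lambda_grid_points))
  n_per <- sims_per_point(config, length(grid))
  alpha <- (1 - config$ci_level) / 2
  probs <- c(alpha, 1 - alpha)
  lo <- hi <- numeric(length(grid))
  for (j in seq_along(grid)) {
    tt <- numeric(n_per)
    for (i in seq_len(nrow(design))) {
      lam <- grid[j] * design$fraction_plated[i] / design$wells_total[i]
      tt <- tt + simulate_plating(lam, design$wells_total[i], n_per)
    }
    qs <- stats::quantile(tt, probs, type = 1, names = FALSE)
    lo[j] <- qs[1]
    hi[j] <- qs[2]
  }
  bands <- monotonise_bands(lo, hi)
  data.frame(N = grid, t_lo = bands$lo, t_hi = bands$hi,
             n_sims_at_point = n_per)
}

#' Grid-inversion confidence interval for whole-transfection clone numbers
#'
#' Builds the clone-number belt for the observed design
#' ([build_clone_bands()]) and inverts it on the observed total
#' positive-well count \eqn{T = \sum_i k_i}.
#'
#' @param plates A plate table (see [estimate_efficiency()]).
#' @param config A [sim_config()].
#' @return A list with `ci_lo`, `ci_hi`, `one_sided`, `saturated`, `empty`,
#'   `n_sims_used`, the observed `statistic` and the `bands` used.
#' @export
efficiency_ci <- function(plates, config = sim_config()) {
  plates <- as_plate_table(plates)
  if (nrow(plates) == 0L) stop("at least one plate observation is required")
  bands <- build_clone_bands(plates, config)
  t_obs <- sum(plates$wells_positive)
  acc <- which(bands$t_lo <= t_obs & t_obs <= bands$t_hi)
  if (!length(acc)) {
    warning("observed counts lie outside every simulated band; empty confidence set")
    return(list(ci_lo = NA_real_, ci_hi = NA_real_, one_sided = FALSE,
                saturated = FALSE, empty = TRUE,
                n_sims_used = sum(bands$n_sims_at_point),
                statistic = t_obs, bands = bands))
  }
  ci_lo <- bands$N[min(acc)]
  ci_hi <- bands$N[max(acc)]
  one_sided <- FALSE
  if (t_obs == 0 && min(acc) == 1L) {
    ci_lo <- 0
    one_sided <- TRUE
  }
  saturated <- max(acc) == nrow(bands)
  if (saturated) one_sided <- TRUE
  list(ci_lo = ci_lo, ci_hi = ci_hi, one_sided = one_sided,
       saturated = saturated, empty = FALSE,
       n_sims_used = sum(bands$n_sims_at_point),
       statistic = t_obs, bands = bands)
}
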