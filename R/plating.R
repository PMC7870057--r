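#' Probability that a well is positive under the Poisson single-hit model
#'
#' Under limiting dilution, the number of clone-founding cells deposited in a
#' well is Poisson with mean `lambda`; a well grows out (is "positive") iff it
#' received at least one, so \eqn{P(\mathrm{positive}) = 1 - e^{-\lambda}}.
#'
#' @param lambda Mean cells per well (non-negative; vectorised).
#' @return Probability in \[0, 1).
#' @examples
#' p_positive(1.5)   # ~0.777 at the nominal replica-plating density
#' @export
p_positive <- function(lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  -expm1(-lambda)
}

#' Maximum-likelihood mean cells per well from positive-well counts
#'
#' Inverts the single-hit model: \eqn{\hat\lambda = -\ln(1 - k/W)} for `k`
#' positive wells of `W`. An all-positive plate carries no upper information
#' on \eqn{\lambda} (the MLE is unbounded) and is rejected here; callers must
#' treat saturated plates as yielding a lower bound only (see
#' [estimate_efficiency()]).
#'
#' @param wells_positive Number of positive wells `k` (vectorised).
#' @param wells_total Number of wells `W` on the plate.
#' @return Cells per well; 0 when `k = 0`.
#' @examples
#' lambda_mle(71, 96)  # 1.346
#' @export
lambda_mle <- function(wells_positive, wells_total) {
  stopifnot(all(wells_total >= 1), all(wells_positive >= 0),
            all(wells_positive <= wells_total))
  if (any(wells_positive == wells_total)) {
    stop("saturated plate (all wells positive): lambda is unbounded; ",
         "treat as a lower bound only")
  }
  -log1p(-wells_positive / wells_total)
}

#' Scale a per-plate density to whole-transfection clone numbers
#'
#' A plate that received fraction `f` of the transfection at `lambda` cells
#' per well across `W` wells implies \eqn{N = \lambda W / f} independent
#' clones in the whole transfection.
#'
#' @param lambda Mean cells (clones) per well.
#' @param wells_total Wells on the plate.
#' @param fraction_plated Fraction of the transfection on the plate, in (0, 1].
#' @return Estimated clones in the whole transfection.
#' @export
clones_from_lambda <- function(lambda, wells_total, fraction_plated) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  stopifnot(all(fraction_plated > 0), all(fraction_plated <= 1))
  lambda * wells_total / fraction_plated
}

#' Joint log-likelihood of a clone number given plate observations
#'
#' For a transfection of `N` independent clones, plate i receives Poisson
#' wells at \eqn{\lambda_i = N f_i / W_i}, so its positive-well count is
#' \eqn{Binomial(W_i, 1 - e^{-N f_i / W_i})}. The joint log-likelihood is the
#' sum of the binomial log-pmfs. Vectorised over `N`.
#'
#' @param N Clone number(s), non-negative.
#' @param plates A plate table (see [read_plate_table()] for the columns).
#' @return Log-likelihood value(s); `-Inf` where the data are impossible
#'   (e.g. `N = 0` with positive wells observed).
#' @export
loglik_clones <- function(N, plates) {
  if (any(N < 0)) stop("N must be non-negative")
  plates <- as_plate_table(plates)
  vapply(N, function(n) {
    p <- p_positive(n * plates$fraction_plated / plates$wells_total)
    # 1 - e^{-lambda} < 1 exactly, but rounds to 1 for large lambda; keep
    # the objective finite for plates with k < W so optimisers can bracket
    p <- pmin(p, 1 - .Machine$double.eps / 2)
    sum(stats::dbinom(plates$wells_positive, plates$wells_total, p, log = TRUE))
  }, numeric(1))
}

#' Estimate transfection efficiency from limiting-dilution plate counts
#'
#' Fits the Poisson single-hit model to one or more plates from the same
#' transfection and returns the maximum-likelihood number of independent
#' stable transfectants, with a simulation-based confidence interval by
#' grid inversion (see [efficiency_ci()]).
#'
#' Multiple plates (typically two plating fractions, e.g. 20% and 4%) are
#' combined through the joint binomial likelihood over a shared clone number
#' `N`; the single-plate case reduces to the closed-form inversion
#' \eqn{\hat N = -\ln(1 - k/W) \cdot W / f}. Saturated plates (all wells
#' positive) contribute their likelihood term; if every plate is saturated
#' the fit degenerates to a one-sided lower bound — the smallest `N` whose
#' probability of producing all-positive wells on every plate exceeds
#' `1 - ci_level` — and is flagged as such.
#'
#' @param plates A plate table: `data.frame` with columns `plate_id`,
#'   `condition`, `wells_total`, `wells_positive`, `fraction_plated`.
#' @param config A [sim_config()] controlling the confidence-belt simulation.
#' @param ci Compute the grid-inversion confidence interval (default `TRUE`;
#'   set `FALSE` for a fast point estimate).
#' @return An object of class `transfection_fit` with components
#'   `clones_hat`, per-plate `lambda_hat`, `ci_lo`, `ci_hi`, `ci_level`,
#'   `one_sided`, `saturated_plates`, `n_sims_used`, the data and the config.
#' @examples
#' pl <- data.frame(plate_id = c("a", "b"), condition = "none",
#'                  wells_total = 96, wells_positive = c(84, 32),
#'                  fraction_plated = c(0.2, 0.04))
#' fit <- estimate_efficiency(pl, sim_config(n_sims = 2e4, seed = 1))
#' fit
#' @seealso [estimate_loss()] for the replica-plating marker-loss model.
#' @export
estimate_efficiency <- function(plates, config = sim_config(), ci = TRUE) {
  plates <- as_plate_table(plates)
  if (nrow(plates) == 0L) stop("at least one plate observation is required")
  k <- plates$wells_positive
  W <- plates$wells_total
  f <- plates$fraction_plated
  sat <- k == W
  saturated_plates <- as.character(plates$plate_id[sat])
  one_sided <- FALSE

  if (all(sat)) {
    # All-saturated: lower bound only. P(all plates all-positive | N) is
    # increasing in N; find where it crosses 1 - ci_level.
    log_p_all <- function(N) sum(W * log(p_positive(N * f / W)))
    target <- log(1 - config$ci_level)
    upper <- 100 * max(W / f) * max(W)
    root <- stats::uniroot(function(N) log_p_all(N) - target,
                           lower = 1e-9, upper = upper, tol = 1e-9)$root
    clones_hat <- Inf
    ci_lo <- root
    ci_hi <- Inf
    one_sided <- TRUE
    n_sims_used <- 0
    warning("all plates saturated: reporting a one-sided lower bound on clone number")
  } else {
    if (all(k == 0)) {
      clones_hat <- 0
    } else if (nrow(plates) == 1L) {
      clones_hat <- clones_from_lambda(lambda_mle(k, W), W, f)
    } else {
      # Bracket the joint MLE from per-plate closed forms; the objective is
      # unimodal in N, so bounded 1-D optimisation on the log scale suffices.
      per_plate <- ifelse(sat, 10 * W / f,
                          ifelse(k == 0, NA_real_, -log1p(-k / W) * W / f))
      rng <- range(per_plate, na.rm = TRUE)
      lo <- max(rng[1] / 100, 1e-8)
      hi <- rng[2] * 100
      opt <- stats::optimize(function(t) loglik_clones(exp(t), plates),
                             interval = log(c(lo, hi)),
                             maximum = TRUE, tol = 1e-10)
      clones_hat <- exp(opt$maximum)
    }
    if (ci) {
      belt <- efficiency_ci(plates, config)
      ci_lo <- belt$ci_lo
      ci_hi <- belt$ci_hi
      one_sided <- belt$one_sided
      n_sims_used <- belt$n_sims_used
    } else {
      ci_lo <- ci_hi <- NA_real_
      n_sims_used <- 0
    }
  }

  structure(
    list(
      clones_hat = clones_hat,
      lambda_hat = stats::setNames(clones_hat * f / W, as.character(plates$plate_id)),
      ci_lo = ci_lo,
      ci_hi = ci_hi,
      ci_level = config$ci_level,
      one_sided = one_sided,
      saturated_plates = saturated_plates,
      n_sims_used = n_sims_used,
      plates = plates,
      config = config,
      call = match.call()
    ),
    class = "transfection_fit"
  )
}

#' @export
print.transfection_fit <- function(x, digits = 3, ...) {
  cat("Limiting-dilution transfection efficiency (Poisson single-hit model)\n")
  cat(sprintf("  plates: %d (%s positive wells of %s)\n",
              nrow(x$plates),
              paste(x$plates$wells_positive, collapse = ", "),
              paste(x$plates$wells_total, collapse = ", ")))
  if (is.finite(x$clones_hat)) {
    cat(sprintf("  independent clones: %s\n",
                format(signif(x$clones_hat, digits))))
  } else {
    cat("  independent clones: not identifiable (all plates saturated)\n")
  }
  if (!is.na(x$ci_lo)) {
    bounds <- format(signif(c(x$ci_lo, x$ci_hi), digits))
    if (x$one_sided && !is.finite(x$ci_hi)) {
      cat(sprintf("  %g%% lower bound: > %s\n", 100 * x$ci_level, bounds[1]))
    } else {
      cat(sprintf("  %g%% CI: [%s, %s]\n", 100 * x$ci_level,
                  bounds[1], bounds[2]))
    }
  }
  if (length(x$saturated_plates)) {
    cat("  saturated plates:", paste(x$saturated_plates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.transfection_fit <- function(object, ...) {
  out <- object
  out$per_plate <- data.frame(
    plate_id = object$plates$plate_id,
    wells_positive = object$plates$wells_positive,
    wells_total = object$plates$wells_total,
    fraction_plated = object$plates$fraction_plated,
    lambda_fitted = as.numeric(object$lambda_hat),
    expected_positive = object$plates$wells_total *
      p_positive(as.numeric(object$lambda_hat))
  )
  class(out) <- c("summary.transfection_fit", class(object))
  out
}

#' @export
print.summary.transfection_fit <- function(x, digits = 3, ...) {
  print.transfection_fit(x, digits = digits, ...)
  cat("\nPer-plate fit:\n")
  print(format(x$per_plate, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.transfection_fit <- function(object, ...) {
  c(clones = object$clones_hat)
}

#' @export
confint.transfection_fit <- function(object, parm = "clones", level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$ci_level))) {
    stop("interval was built at ci_level = ", object$ci_level,
         "; refit with a different sim_config to change it")
  }
  matrix(c(object$ci_lo, object$ci_hi), nrow = 1,
         dimnames = list("clones",
                         sprintf("%g %%", 100 * c((1 - object$ci_level) / 2,
                                                  1 - (1 - object$ci_level) / 2))))
}

#' @export
logLik.transfection_fit <- function(object, ...) {
  val <- if (is.finite(object$clones_hat)) {
    loglik_clones(object$clones_hat, object$plates)
  } else NA_real_
  structure(val, df = 1, class = "logLik")
}

#' @export
predict.transfection_fit <- function(object, newdata = NULL, ...) {
  design <- if (is.null(newdata)) object$plates else as_plate_design(newdata)
  design$wells_total *
    p_positive(object$clones_hat * design$fraction_plated / design$wells_total)
}

#' @export
simulate.transfection_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- object$plates[c("plate_id", "condition", "wells_total",
                            "fraction_plated")]
  lapply(seq_len(nsim), function(i) {
    gen_transfection(object$clones_hat, design)
  })
}

#' @export
plot.transfection_fit <- function(x, n_points = 200, ...) {
  if (!is.finite(x$clones_hat)) {
    stop("profile plot unavailable for an all-saturated fit")
  }
  lo <- max(x$clones_hat / 20, 1e-3)
  hi <- max(x$clones_hat * 20, 1)
  if (!is.na(x$ci_lo) && x$ci_lo > 0) lo <- min(lo, x$ci_lo / 2)
  if (!is.na(x$ci_hi) && is.finite(x$ci_hi)) hi <- max(hi, x$ci_hi * 2)
  grid <- exp(seq(log(lo), log(hi), length.out = n_points))
  ll <- loglik_clones(grid, x$plates)
  graphics::plot(grid, ll - max(ll), type = "l", log = "x",
                 xlab = "independent clones N",
                 ylab = "relative log-likelihood", ...)
  graphics::abline(v = x$clones_hat, lty = 2)
  if (!is.na(x$ci_lo)) {
    graphics::abline(v = c(x$ci_lo, x$ci_hi), lty = 3, col = "grey40")
  }
  invisible(x)
}
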