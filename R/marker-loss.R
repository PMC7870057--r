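#' Probability that a populated well is drug-sensitive
#'
#' In the replica-plating experiment, each well receives a Poisson number of
#' founder cells (mean `lambda`) of which each has independently lost the
#' selectable marker with probability `q` before plating. A populated well
#' is drug-sensitive iff every founder lost the marker, so conditioning on
#' at least one founder,
#' \deqn{P(\mathrm{sensitive} \mid \mathrm{populated}) =
#'   \frac{e^{-\lambda(1-q)} - e^{-\lambda}}{1 - e^{-\lambda}}.}
#' As \eqn{\lambda \to 0} every populated well is clonal and the probability
#' tends to `q`; that analytic limit is used at `lambda = 0`.
#'
#' @param lambda Mean cells per well (non-negative; vectorised).
#' @param q Per-cell marker-loss probability in \[0, 1\] (vectorised).
#' @return Probability in \[0, 1\]; strictly increasing in `q`.
#' @examples
#' p_sensitive(1.5686, 0.167)  # ~0.079, the 6/76 regime
#' @export
p_sensitive <- function(lambda, q) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  # e^{-l(1-q)} - e^{-l} = e^{-l} expm1(l q);  1 - e^{-l} = -expm1(-l)
  p <- ifelse(lambda < 1e-12, q,
              exp(-lambda) * expm1(lambda * q) / (-expm1(-lambda)))
  pmin(pmax(p, 0), 1)
}

#' Closed-form estimate of the per-cell marker-loss probability
#'
#' Inverts [p_sensitive()] at the observed sensitive fraction `s/n`:
#' \deqn{\hat q = 1 + \ln\!\big(\tfrac{s}{n}(1 - e^{-\lambda}) +
#'   e^{-\lambda}\big) / \lambda.}
#' This is the maximum-likelihood estimate of `q` given \eqn{\lambda}
#' because the sensitive count is binomial in the sensitive probability.
#' The boundary cases are exact: `q_mle(0, n, lambda) = 0` and
#' `q_mle(n, n, lambda) = 1`.
#'
#' @param sensitive_wells Wells positive without drug but negative with
#'   drug (`s`).
#' @param populated_wells Wells positive on the no-drug replica (`n`).
#' @param lambda Mean cells per well at plating (> 0).
#' @return Estimate of `q` in \[0, 1\].
#' @examples
#' q_mle(6, 76, lambda_mle(76, 96))  # ~0.167
#' @export
q_mle <- function(sensitive_wells, populated_wells, lambda) {
  stopifnot(all(populated_wells >= 1),
            all(sensitive_wells >= 0),
            all(sensitive_wells <= populated_wells))
  if (any(lambda <= 0)) stop("lambda must be positive")
  frac <- sensitive_wells / populated_wells
  q <- 1 + log(frac * (-expm1(-lambda)) + exp(-lambda)) / lambda
  q <- ifelse(sensitive_wells == 0, 0, ifelse(frac == 1, 1, q))
  pmin(pmax(q, 0), 1)
}

#' Delta-method standard error of the cells-per-well estimate
#'
#' For \eqn{\hat\lambda = -\ln(1 - k/W)} with \eqn{\hat p = k/W},
#' \eqn{SE(\hat\lambda) = \sqrt{\hat p / (W (1 - \hat p))}}. Undefined at
#' `k = 0` or `k = W`; callers then fall back to a nominal plating density
#' with an explicit spread (see [estimate_loss()]).
#'
#' @param wells_positive Positive wells `k`, with `0 < k < W`.
#' @param wells_total Wells `W`.
#' @return Positive standard error.
#' @examples
#' lambda_se(76, 96)  # ~0.199
#' @export
lambda_se <- function(wells_positive, wells_total) {
  stopifnot(all(wells_total >= 1))
  if (any(wells_positive <= 0) || any(wells_positive >= wells_total)) {
    stop("lambda_se is undefined at k = 0 or k = W; ",
         "use a nominal lambda with an explicit spread instead")
  }
  p <- wells_positive / wells_total
  sqrt(p / (wells_total * (1 - p)))
}

#' Estimate per-cell marker-loss probability from replica plating
#'
#' Fits the compound zero-truncated-Poisson/binomial loss model to one
#' replica-plating experiment: `populated_wells` of `wells_total` grew
#' without drug, of which `sensitive_wells` failed to grow under drug.
#' The point estimate is the closed-form [q_mle()] at
#' \eqn{\hat\lambda = -\ln(1 - n/W)}. The confidence interval is built by
#' grid inversion: for each `q` on a grid over \[0, 1\], platings are
#' simulated with the plating density resampled
#' (\eqn{\lambda^* \sim} Normal(\eqn{\hat\lambda}, SE), truncated at 0;
#' populated \eqn{\sim Binomial(W, 1 - e^{-\lambda^*})}; sensitive
#' \eqn{\sim Binomial(\mathrm{populated}, p_{\mathrm{sensitive}})}), and
#' `q` is accepted when the observed sensitive count lies within the
#' equal-tailed `ci_level` band of the simulated counts. Band edges are
#' monotonised in `q` (widening-only). An interval whose endpoint sits on
#' the parameter boundary (`s = 0` or `s = n`) is flagged `one_sided`.
#'
#' If the initial grid accepts nothing (possible only under an extreme
#' budget/step combination), the grid step is refined once, with a warning.
#'
#' @param wells_total Wells on the plate (`W`, typically 96).
#' @param populated_wells Positive wells on the no-drug replica (`n`).
#' @param sensitive_wells Wells lost under drug (`s`).
#' @param nominal_lambda Optional plating density used as a fallback when
#'   `n = 0` or `n = W` leaves \eqn{\lambda} inestimable (e.g. the nominal
#'   1.5 cells per well).
#' @param lambda,lambda_sd Optional explicit override of the estimated
#'   plating density and its resampling spread.
#' @param clone_id,condition Optional labels carried into the fit.
#' @param config A [sim_config()]; `q_grid_step` sets the grid, `n_sims`
#'   the total budget (divided across grid points), `ci_level` the
#'   coverage, `seed` the RNG.
#' @return An object of class `loss_fit` with components `q_hat`,
#'   `lambda_hat`, `lambda_sd`, `ci_lo`, `ci_hi`, `ci_level`, `one_sided`,
#'   `n_sims_used`, the data, the accepted grid and the config.
#' @examples
#' fit <- estimate_loss(96, 76, 6, config = sim_config(n_sims = 1e5, seed = 1))
#' fit
#' @export
estimate_loss <- function(wells_total, populated_wells, sensitive_wells,
                          nominal_lambda = NULL,
                          lambda = NULL, lambda_sd = NULL,
                          clone_id = NULL, condition = NULL,
                          config = sim_config()) {
  W <- wells_total
  n <- populated_wells
  s <- sensitive_wells
  stopifnot(W >= 1, n >= 0, n <= W, s >= 0, s <= n)
  if (n == 0) stop("no populated wells: the loss probability is inestimable")

  if (is.null(lambda)) {
    if (n < W) {
      lambda <- lambda_mle(n, W)
      if (is.null(lambda_sd)) lambda_sd <- lambda_se(n, W)
    } else {
      if (is.null(nominal_lambda)) {
        stop("all wells populated: lambda is inestimable from this plate; ",
             "supply nominal_lambda (or lambda/lambda_sd)")
      }
      lambda <- nominal_lambda
      # Spread is not identifiable from a saturated plate; a 20% relative
      # spread on the nominal density is used unless overridden.
      if (is.null(lambda_sd)) lambda_sd <- 0.2 * nominal_lambda
      warning("plate saturated: using nominal_lambda = ", nominal_lambda,
              " with resampling sd ", signif(lambda_sd, 3))
    }
  } else if (is.null(lambda_sd)) {
    lambda_sd <- if (n < W) lambda_se(n, W) else 0.2 * lambda
  }
  stopifnot(lambda > 0, lambda_sd >= 0)

  maybe_set_seed(config)
  belt <- loss_belt(W, lambda, lambda_sd, config)
  acc <- which(belt$s_lo <= s & s <= belt$s_hi)
  if (!length(acc)) {
    warning("empty acceptance set; refining the loss-probability grid 5-fold")
    cfg2 <- config
    cfg2$q_grid_step <- config$q_grid_step / 5
    cfg2$n_sims <- config$n_sims * 5
    belt <- loss_belt(W, lambda, lambda_sd, cfg2)
    acc <- which(belt$s_lo <= s & s <= belt$s_hi)
  }
  if (!length(acc)) {
    ci_lo <- ci_hi <- NA_real_
    empty <- TRUE
    one_sided <- FALSE
  } else {
    ci_lo <- belt$q[min(acc)]
    ci_hi <- belt$q[max(acc)]
    empty <- FALSE
    one_sided <- (s == 0 && ci_lo == 0) || (s == n && ci_hi == 1)
  }

  structure(
    list(
      q_hat = q_mle(s, n, lambda),
      lambda_hat = lambda,
      lambda_sd = lambda_sd,
      ci_lo = ci_lo,
      ci_hi = ci_hi,
      ci_level = config$ci_level,
      one_sided = one_sided,
      empty = empty,
      wells_total = W,
      populated_wells = n,
      sensitive_wells = s,
      clone_id = clone_id,
      condition = condition,
      n_sims_used = sum(belt$n_sims_at_point),
      belt = belt,
      config = config,
      call = match.call()
    ),
    class = "loss_fit"
  )
}

# Simulated equal-tailed bands of sensitive-well counts across the q grid.
loss_belt <- function(W, lambda, lambda_sd, config) {
  qs <- seq(0, 1, by = config$q_grid_step)
  n_per <- sims_per_point(config, length(qs))
  alpha <- (1 - config$ci_level) / 2
  probs <- c(alpha, 1 - alpha)
  lo <- hi <- numeric(length(qs))
  for (i in seq_along(qs)) {
    lam <- stats::rnorm(n_per, lambda, lambda_sd)
    lam[lam <= 0] <- 1e-9  # truncate at zero
    populated <- stats::rbinom(n_per, W, p_positive(lam))
    sens <- stats::rbinom(n_per, populated, p_sensitive(lam, qs[i]))
    b <- stats::quantile(sens, probs, type = 1, names = FALSE)
    lo[i] <- b[1]
    hi[i] <- b[2]
  }
  bands <- monotonise_bands(lo, hi)
  data.frame(q = qs, s_lo = bands$lo, s_hi = bands$hi,
             n_sims_at_point = n_per)
}

#' @export
print.loss_fit <- function(x, digits = 2, ...) {
  cat("Replica-plating marker-loss fit (zero-truncated Poisson / binomial)\n")
  if (!is.null(x$clone_id) || !is.null(x$condition)) {
    cat(sprintf("  experiment: %s%s\n",
                if (is.null(x$clone_id)) "" else paste0(x$clone_id, " "),
                if (is.null(x$condition)) "" else paste0("(", x$condition, ")")))
  }
  cat(sprintf("  sensitive wells: %d of %d populated (of %d)\n",
              x$sensitive_wells, x$populated_wells, x$wells_total))
  cat(sprintf("  cells per well:  %.3f (resampling sd %.3f)\n",
              x$lambda_hat, x$lambda_sd))
  cat(sprintf("  per-cell loss probability: %s\n",
              format(round(x$q_hat, digits), nsmall = digits)))
  if (x$empty) {
    cat("  confidence set: empty (see warnings)\n")
  } else if (x$one_sided && x$sensitive_wells == 0) {
    cat(sprintf("  %g%% upper bound: <= %s\n", 100 * x$ci_level,
                format(round(x$ci_hi, digits), nsmall = digits)))
  } else {
    cat(sprintf("  %g%% CI: [%s, %s]%s\n", 100 * x$ci_level,
                format(round(x$ci_lo, digits), nsmall = digits),
                format(round(x$ci_hi, digits), nsmall = digits),
                if (x$one_sided) " (one-sided: boundary)" else ""))
  }
  invisible(x)
}

#' @export
summary.loss_fit <- function(object, ...) {
  object$expected_sensitive <- object$populated_wells *
    p_sensitive(object$lambda_hat, object$q_hat)
  class(object) <- c("summary.loss_fit", class(object))
  object
}

#' @export
print.summary.loss_fit <- function(x, digits = 2, ...) {
  print.loss_fit(x, digits = digits, ...)
  cat(sprintf("  expected sensitive wells at fit: %.1f (observed %d)\n",
              x$expected_sensitive, x$sensitive_wells))
  cat(sprintf("  simulated platings used: %g\n", x$n_sims_used))
  invisible(x)
}

#' @export
coef.loss_fit <- function(object, ...) {
  c(q = object$q_hat, lambda = object$lambda_hat)
}

#' @export
confint.loss_fit <- function(object, parm = "q", level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$ci_level))) {
    stop("interval was built at ci_level = ", object$ci_level,
         "; refit with a different sim_config to change it")
  }
  matrix(c(object$ci_lo, object$ci_hi), nrow = 1,
         dimnames = list("q",
                         sprintf("%g %%", 100 * c((1 - object$ci_level) / 2,
                                                  1 - (1 - object$ci_level) / 2))))
}

#' @export
predict.loss_fit <- function(object, lambda = NULL, ...) {
  lam <- if (is.null(lambda)) object$lambda_hat else lambda
  p_sensitive(lam, object$q_hat)
}

#' @export
simulate.loss_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    gen_loss_experiment(object$q_hat, object$lambda_hat, object$wells_total,
                        clone_id = object$clone_id,
                        condition = object$condition)
  })
}

#' @export
plot.loss_fit <- function(x, ...) {
  b <- x$belt
  graphics::plot(b$q, b$s_hi, type = "s", ylim = c(0, max(b$s_hi)),
                 xlab = "per-cell loss probability q",
                 ylab = "sensitive wells", ...)
  graphics::lines(b$q, b$s_lo, type = "s")
  graphics::abline(h = x$sensitive_wells, lty = 2)
  graphics::abline(v = c(x$ci_lo, x$ci_hi), lty = 3, col = "grey40")
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Convenience wrapper for comparing sensitive-well proportions between
#' conditions: the two-sided p-value by the minimum-likelihood convention
#' (summing hypergeometric probabilities no larger than that of the
#' observed table), as computed by [stats::fisher.test()]. A table with a
#' zero margin gives p = 1.
#'
#' @param table A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector filled by row.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(matrix(c(0, 71, 6, 70), 2, byrow = TRUE))  # ~0.029
#' @export
fisher_exact_two_sided <- function(table) {
  if (!is.matrix(table)) {
    stopifnot(length(table) == 4)
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Convert a total loss fraction to a per-generation loss probability
#'
#' If a fraction `p_total` of cells lost the marker over `duration_h` hours
#' while doubling every `doubling_h` hours, the per-generation loss
#' probability under independent per-generation loss is
#' \deqn{1 - (1 - p_{total})^{d/t}} with `d = doubling_h`,
#' `t = duration_h` (i.e. the total is spread over `t/d` generations).
#'
#' @param p_total Fraction of cells lost over the interval, in \[0, 1\].
#' @param duration_h Interval length in hours.
#' @param doubling_h Population doubling time in hours.
#' @return Per-generation loss probability in \[0, `p_total`\].
#' @examples
#' per_generation_loss(0.17, 48, 10.3)  # ~0.039
#' @export
per_generation_loss <- function(p_total, duration_h, doubling_h) {
  stopifnot(p_total >= 0, p_total <= 1, duration_h > 0, doubling_h > 0)
  if (p_total == 1) return(1)
  1 - (1 - p_total)^(doubling_h / duration_h)
}
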