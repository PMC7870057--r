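# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-formula re-implementations, exact
# enumeration, and closed forms.

# Two-sided Fisher exact p-value by brute-force enumeration of all tables
# with the observed margins (minimum-likelihood convention).
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Clopper-Pearson interval for a binomial proportion, mapped through the
# single-hit model to cells per well.
cp_lambda_interval <- function(k, W, level = 0.90) {
  a <- (1 - level) / 2
  p_lo <- if (k == 0) 0 else qbeta(a, k, W - k + 1)
  p_hi <- if (k == W) 1 else qbeta(1 - a, k + 1, W - k)
  -log(1 - c(p_lo, p_hi))
}

# Sensitive-well probability, coded directly from the naive formula.
p_sens_naive <- function(l, q) {
  (exp(-l * (1 - q)) - exp(-l)) / (1 - exp(-l))
}

# Invert p_sens_naive at a target fraction by bisection.
q_from_fraction_bisect <- function(frac, lambda, tol = 1e-12) {
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (p_sens_naive(lambda, mid) < frac) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Grid-search maximiser of the joint clone-number likelihood (1-D oracle).
grid_mle_clones <- function(plates, n_grid = 1e4, lo = NULL, hi = NULL) {
  if (is.null(lo)) lo <- 1
  if (is.null(hi)) {
    hi <- 50 * max(plates$wells_total / plates$fraction_plated)
  }
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  ll <- vapply(grid, function(N) {
    p <- 1 - exp(-N * plates$fraction_plated / plates$wells_total)
    sum(dbinom(plates$wells_positive, plates$wells_total, p, log = TRUE))
  }, numeric(1))
  grid[which.max(ll)]
}

# Standard two-plate designs used throughout: routine (20%/4%) and
# high-efficiency (2%/0.4%) platings of 96-well plates.
design_routine <- data.frame(wells_total = 96, fraction_plated = c(0.2, 0.04))
design_highcap <- data.frame(wells_total = 96, fraction_plated = c(0.02, 0.004))
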