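test_that("simulate_plating matches binomial single-hit moments", {
  set.seed(1)
  expect_identical(simulate_plating(0, 96, 5), rep(0L, 5))
  k <- simulate_plating(1.5, 96, 1e5)
  # mean 96 (1 - e^-1.5) = 74.58, MC SE ~0.013
  expect_equal(mean(k), 96 * (1 - exp(-1.5)), tolerance = 1e-3)
  # near-saturating density: all wells positive with prob ~ 1 - 96 e^-10
  k10 <- simulate_plating(10, 96, 1e4)
  expect_equal(mean(k10 == 96), 1 - 96 * exp(-10) * (1 - exp(-10))^95,
               tolerance = 5e-3)
})

test_that("simulated bands track exact binomial quantiles and are monotone", {
  cfg <- sim_config(n_sims = 2e6, lambda_grid_points = 60, seed = 42)
  bands <- build_quantile_bands(96, cfg)
  expect_true(all(diff(bands$k_lo) >= 0))
  expect_true(all(diff(bands$k_hi) >= 0))
  expect_true(all(bands$k_lo <= bands$k_hi))
  expect_true(all(bands$k_lo >= 0 & bands$k_hi <= 96))
  p <- 1 - exp(-bands$lambda)
  expect_true(all(abs(bands$k_lo - qbinom(0.05, 96, p)) <= 1))
  expect_true(all(abs(bands$k_hi - qbinom(0.95, 96, p)) <= 1))
  # band at the bottom of the default grid: 0 or 1 positive wells
  expect_lte(bands$k_hi[1], 1)
})

test_that("a tiny budget per grid point warns", {
  expect_warning(build_quantile_bands(96, sim_config(n_sims = 1e3, seed = 1)),
                 "budget")
})

test_that("zero-width level gives degenerate bands at the median", {
  cfg <- sim_config(n_sims = 5e4, lambda_grid_points = 20, ci_level = 1e-9,
                    seed = 3)
  bands <- build_quantile_bands(96, cfg)
  med <- qbinom(0.5, 96, 1 - exp(-bands$lambda))
  expect_true(all(abs(bands$k_hi - bands$k_lo) <= 2))
  expect_true(all(abs(bands$k_lo - med) <= 2))
})

test_that("invert_ci brackets the point estimate and flags the edges", {
  cfg <- sim_config(n_sims = 1e6, seed = 11)
  bands <- build_quantile_bands(96, cfg)

  res <- invert_ci(50, bands)
  lam_hat <- lambda_mle(50, 96)  # 0.7357
  expect_true(res[1] <= lam_hat && lam_hat <= res[2])
  cp <- cp_lambda_interval(50, 96)
  expect_true(res[1] <= cp[1] * 1.1 && res[2] >= cp[2] / 1.1)

  res0 <- invert_ci(0, bands)
  expect_identical(res0[[1]], 0)
  expect_true(attr(res0, "one_sided"))

  res96 <- invert_ci(96, bands)
  expect_true(attr(res96, "saturated"))
  expect_equal(res96[[2]], cfg$lambda_grid_max, tolerance = 1e-9)
})

test_that("identical config and seed give identical intervals", {
  cfg <- sim_config(n_sims = 1e5, lambda_grid_points = 50, seed = 99)
  b1 <- build_quantile_bands(96, cfg)
  b2 <- build_quantile_bands(96, cfg)
  expect_identical(b1, b2)
  pl <- data.frame(plate_id = "a", condition = "x", wells_total = 96,
                   wells_positive = 30, fraction_plated = 0.2)
  expect_identical(efficiency_ci(pl, cfg)[c("ci_lo", "ci_hi")],
                   efficiency_ci(pl, cfg)[c("ci_lo", "ci_hi")])
})

test_that("all-negative plate yields the closed-form one-sided upper bound", {
  # accept N while P(no positive well) = e^{-N f} >= alpha/2,
  # so the upper endpoint is -log(alpha/2) / f
  cfg <- sim_config(n_sims = 4e5, lambda_grid_points = 300, seed = 5)
  pl <- data.frame(plate_id = "a", condition = "x", wells_total = 96,
                   wells_positive = 0, fraction_plated = 0.2)
  res <- efficiency_ci(pl, cfg)
  expect_identical(res$ci_lo, 0)
  expect_true(res$one_sided)
  n_hi_exact <- -log(0.05) / 0.2
  step <- exp(log(10 / 0.001) / (cfg$lambda_grid_points - 1))
  expect_lt(abs(log(res$ci_hi) - log(n_hi_exact)), 2 * log(step))
})

test_that("the interval brackets the joint MLE even for discordant plates", {
  # a draw whose dilute plate ran high: the total-count belt must still
  # contain the likelihood maximiser
  pl <- data.frame(plate_id = c("a", "b"), condition = "x", wells_total = 96,
                   wells_positive = c(80, 44), fraction_plated = c(0.2, 0.04))
  fit <- estimate_efficiency(pl, sim_config(n_sims = 2e5, seed = 42))
  expect_true(fit$ci_lo <= fit$clones_hat && fit$clones_hat <= fit$ci_hi)
})

test_that("plating a larger fraction narrows the clone-number interval", {
  cfg <- sim_config(n_sims = 2e5, lambda_grid_points = 150, seed = 13)
  N <- 1000
  widths <- vapply(c(0.04, 0.2), function(f) {
    k <- round(96 * p_positive(N * f / 96))
    pl <- data.frame(plate_id = "a", condition = "x", wells_total = 96,
                     wells_positive = k, fraction_plated = f)
    res <- efficiency_ci(pl, cfg)
    (res$ci_hi - res$ci_lo) / N
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("widening the nominal level widens the interval towards the grid", {
  pl <- data.frame(plate_id = "a", condition = "x", wells_total = 96,
                   wells_positive = 30, fraction_plated = 0.2)
  cfg_mid <- sim_config(n_sims = 1e5, lambda_grid_points = 40,
                        ci_level = 0.5, seed = 2)
  cfg_ext <- sim_config(n_sims = 1e5, lambda_grid_points = 40,
                        ci_level = 1 - 1e-9, seed = 2)
  mid <- efficiency_ci(pl, cfg_mid)
  ext <- efficiency_ci(pl, cfg_ext)
  # at ci_level -> 1 the belt is the simulated min/max, so the accepted
  # set strictly contains the mid-level interval
  expect_lt(ext$ci_lo, mid$ci_lo)
  expect_gt(ext$ci_hi, mid$ci_hi)
})

test_that("relative interval width is below 1 across each design's stated range", {
  # the two standard designs are built to resolve 100-6000 and 1000-60000
  # clones; relative 90% CI width stays under 1 across those ranges
  cfg <- sim_config(n_sims = 4e5, lambda_grid_points = 200, seed = 21)
  check_design <- function(design, range_n) {
    bands <- build_clone_bands(design, cfg)
    for (N in exp(seq(log(range_n[1]), log(range_n[2]), length.out = 7))) {
      k <- round(design$wells_total *
                   p_positive(N * design$fraction_plated / design$wells_total))
      t_obs <- sum(k)
      acc <- which(bands$t_lo <= t_obs & t_obs <= bands$t_hi)
      expect_gt(length(acc), 0)
      width <- (bands$N[max(acc)] - bands$N[min(acc)]) / N
      expect_lt(width, 1.0)
    }
  }
  check_design(design_routine, c(100, 6000))
  check_design(design_highcap, c(1000, 60000))
})
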