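test_that("p_sensitive follows the compound model with exact limits", {
  # single-cell limit: a populated well holds one founder, so P = q
  expect_equal(p_sensitive(0, 0.3), 0.3)
  expect_equal(p_sensitive(1e-14, 0.3), 0.3)
  expect_equal(p_sensitive(1.5686, 0.167), 0.0789, tolerance = 2e-3)
  # the exact point inverse of the observed 6/76 sensitive fraction
  expect_equal(p_sensitive(1.5686, q_mle(6, 76, 1.5686)), 6 / 76)
  expect_equal(p_sensitive(1.5686, 0.167), p_sens_naive(1.5686, 0.167))
  lam <- c(0.2, 1.5, 4)
  expect_equal(p_sensitive(lam, 1), rep(1, 3))
  expect_equal(p_sensitive(lam, 0), rep(0, 3))
  # strictly increasing in q, in [0, 1]
  q <- seq(0, 1, by = 0.05)
  p <- p_sensitive(1.5, q)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(p_sensitive(-1, 0.5))
  expect_error(p_sensitive(1, 1.5))
})

test_that("q_mle inverts p_sensitive exactly across the domain", {
  for (lam in c(0.2, 0.5, 1.346, 1.5686, 3, 6)) {
    for (s in c(0, 1, 3, 20, 50, 76)) {
      q <- q_mle(s, 76, lam)
      expect_lt(abs(p_sensitive(lam, q) - s / 76), 1e-10)
    }
  }
  expect_identical(q_mle(0, 71, 1.346), 0)
  expect_identical(q_mle(76, 76, 1.5686), 1)
  expect_equal(q_mle(6, 76, 1.5686), 0.167, tolerance = 2e-3)
  # agrees with bisection on the naive formula
  expect_equal(q_mle(6, 76, 1.5686),
               q_from_fraction_bisect(6 / 76, 1.5686), tolerance = 1e-9)
  expect_error(q_mle(6, 76, 0), "positive")
  expect_error(q_mle(7, 6, 1))
})

test_that("lambda_se matches the delta method and a parametric bootstrap", {
  expect_equal(lambda_se(76, 96), sqrt((76 / 96) / (96 * (1 - 76 / 96))))
  expect_equal(lambda_se(76, 96), 0.199, tolerance = 1e-3)
  expect_equal(lambda_se(48, 96), sqrt(0.5 / (96 * 0.5)))
  # bootstrap oracle: sd of lambda_mle over resimulated plates
  set.seed(4)
  k <- rbinom(2e4, 96, 76 / 96)
  k <- k[k > 0 & k < 96]
  boot_sd <- sd(-log(1 - k / 96))
  expect_equal(lambda_se(76, 96), boot_sd, tolerance = 0.05)
  # shrinks with plate size at fixed proportion
  expect_lt(lambda_se(1e4, 2e4), lambda_se(50, 100))
  expect_error(lambda_se(0, 96), "undefined")
  expect_error(lambda_se(96, 96), "undefined")
})

test_that("loss fit reproduces the replica-plating point estimates and belts", {
  cfg <- sim_config(n_sims = 4e5, q_grid_step = 0.005, seed = 8)
  fit <- estimate_loss(96, 76, 6, config = cfg)
  expect_s3_class(fit, "loss_fit")
  expect_equal(fit$lambda_hat, lambda_mle(76, 96))
  expect_equal(fit$q_hat, q_mle(6, 76, fit$lambda_hat))
  # interval always contains the point estimate
  expect_true(fit$ci_lo <= fit$q_hat && fit$q_hat <= fit$ci_hi)
  expect_false(fit$one_sided)

  fit0 <- estimate_loss(96, 71, 0, config = cfg)
  expect_identical(fit0$q_hat, 0)
  expect_identical(fit0$ci_lo, 0)
  expect_true(fit0$one_sided)

  fit_all <- estimate_loss(96, 76, 76, config = cfg)
  expect_identical(fit_all$q_hat, 1)
  expect_identical(fit_all$ci_hi, 1)
  expect_true(fit_all$one_sided)
})

test_that("the s = 0 upper bound tightens with plate size at fixed density", {
  # at a fixed plating density, a bigger plate with not a single sensitive
  # well is more evidence against loss, so the bound shrinks with W.
  # (With lambda re-estimated from the same plate the bound is NOT monotone
  # in the populated count: a nearly saturated plate implies many founders
  # per well, which weakens the per-cell evidence again.)
  cfg <- sim_config(n_sims = 2e6, q_grid_step = 0.005, seed = 15)
  ub <- vapply(c(24, 48, 96, 192), function(W) {
    estimate_loss(W, round(W * 0.7), 0, lambda = 1.5, lambda_sd = 0.15,
                  config = cfg)$ci_hi
  }, numeric(1))
  # non-increasing up to one grid step of Monte-Carlo ripple
  expect_true(all(diff(ub) <= cfg$q_grid_step + 1e-12))
  expect_lt(ub[4], ub[1])
})

test_that("inestimable plating densities fall back to the nominal density", {
  expect_error(estimate_loss(96, 0, 0), "inestimable")
  expect_error(estimate_loss(96, 96, 10, config = sim_config(n_sims = 2e4)),
               "nominal_lambda")
  expect_warning(
    fit <- estimate_loss(96, 96, 10, nominal_lambda = 1.5,
                         config = sim_config(n_sims = 5e4, seed = 2)),
    "saturated")
  expect_equal(fit$lambda_hat, 1.5)
  expect_equal(fit$lambda_sd, 0.3)
})

test_that("loss_fit methods are coherent", {
  cfg <- sim_config(n_sims = 1e5, seed = 5)
  fit <- estimate_loss(96, 76, 6, clone_id = "c1", condition = "induced",
                       config = cfg)
  expect_named(coef(fit), c("q", "lambda"))
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), c(fit$ci_lo, fit$ci_hi))
  expect_equal(predict(fit), p_sensitive(fit$lambda_hat, fit$q_hat))
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_true(all(vapply(sims, function(s)
    s$sensitive_wells <= s$populated_wells, logical(1))))
  expect_output(print(summary(fit)), "expected sensitive")
})

test_that("two-sided Fisher p-values match brute-force enumeration", {
  tables <- list(
    matrix(c(0, 71, 6, 70), 2, byrow = TRUE),
    matrix(c(11, 185, 0, 71), 2, byrow = TRUE),
    matrix(c(1, 1, 1, 1), 2),
    matrix(c(5, 0, 0, 5), 2),
    matrix(c(12, 34, 27, 8), 2),
    matrix(c(3, 97, 9, 91), 2, byrow = TRUE)
  )
  for (tab in tables) {
    expect_equal(fisher_exact_two_sided(tab), fisher_enum(tab),
                 tolerance = 1e-9)
  }
  expect_identical(fisher_exact_two_sided(matrix(c(1, 1, 1, 1), 2)), 1)
  # zero margin: no evidence either way
  expect_identical(fisher_exact_two_sided(matrix(c(0, 0, 5, 7), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_two_sided(c(1, 2, 3)))
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)))
})

test_that("per-generation conversion follows the compounding formula", {
  expect_identical(per_generation_loss(0, 48, 10.3), 0)
  expect_equal(per_generation_loss(0.17, 48, 10.3), 1 - 0.83^(10.3 / 48))
  expect_equal(per_generation_loss(0.17, 48, 10.3), 0.039, tolerance = 1e-2)
  expect_equal(per_generation_loss(0.5, 7, 7), 0.5)
  expect_identical(per_generation_loss(1, 48, 10.3), 1)
  expect_error(per_generation_loss(0.5, 0, 10))
  expect_error(per_generation_loss(1.2, 48, 10))
})
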