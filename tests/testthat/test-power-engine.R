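test_that("critical_value is the upper-alpha F quantile", {
  # monotone decreasing in alpha
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  cv <- vapply(alphas, function(a) critical_value(2, 30, a), 0.0)
  expect_true(all(diff(cv) > 0))

  # large-denominator limit: F(2, m) quantile -> chi2(2) quantile / 2
  expect_equal(critical_value(2, 1e7, 0.05), qchisq(0.95, 2) / 2,
               tolerance = 1e-4)

  # independent quantile route via the beta representation of the F CDF:
  # if X ~ F(d1, d2) then d1 X / (d1 X + d2) ~ Beta(d1/2, d2/2)
  qb <- qbeta(0.95, 1, 97 / 2)
  expect_equal(critical_value(2, 97, 0.05), (97 / 2) * qb / (1 - qb),
               tolerance = 1e-8)

  expect_error(critical_value(2, 30, 1.5), class = "jointpwr_input_error")
  expect_error(critical_value(0, 30, 0.05), class = "jointpwr_input_error")
})

test_that("conditional power is calibrated, monotone, and matches simulation", {
  eff0 <- effect_spec(c(1, 2), c(1, 2), 1)
  des <- design_summary(0.5, 9, 20)
  expect_equal(power_conditional(eff0, des, 0.05)$power, 0.05)

  # diverges to 1 as the noncentrality grows
  eff_big <- effect_spec(c(100, 2), c(0, 2), 1)
  expect_gt(power_conditional(eff_big, des, 0.05)$power, 0.9999)

  # Monte Carlo of the test on a fixed design, via the closed-form oracle
  eff <- effect_spec(c(0.3, 1.3), c(0, 1), 1)
  n <- 20
  x <- fixed_design_x(n, xbar = 0.0606531, ssx = 9)
  delta <- conditional_noncentrality(
    eff, design_summary(mean(x), sum((x - mean(x))^2), n))
  pw <- power_conditional(
    eff, design_summary(mean(x), sum((x - mean(x))^2), n), 0.05)$power
  R <- 200000
  emp <- oracle_mc_power(c(0.3, 1.3), c(0, 1), 1, n, 0.05, R, seed = 101,
                         fixed_x = x)
  expect_lt(abs(pw - emp), 3.5 * mc_se(pw, R))
  expect_gt(delta, 0)
})

test_that("approximate power reproduces the published mean-substitution values", {
  # nine-cell study, mu_X = 0, sigma2_X = 2: exact minimal N is 53
  expect_equal(power_approx(grid_effect(0.3), predictor_spec(0, 2), 53)$power,
               0.4602, tolerance = 1e-4)
  # fetal configuration at the approximate method's minimal sizes
  expect_equal(power_approx(fetal_effect(), fetal_predictor(), 183)$power,
               0.8010, tolerance = 1e-4)
  expect_equal(power_approx(fetal_effect(), fetal_predictor(), 239)$power,
               0.9002, tolerance = 1e-4)
  # null effect gives power alpha
  expect_equal(power_approx(effect_spec(c(1, 2), c(1, 2), 1),
                            predictor_spec(0, 1), 30, 0.05)$power, 0.05)
})

test_that("exact power reproduces the published two-stage mixture values", {
  expect_equal(power_exact(fetal_effect(), fetal_predictor(), 173)$power,
               0.8001, tolerance = 2e-4)
  expect_equal(power_exact(fetal_effect(), fetal_predictor(), 183)$power,
               0.8236, tolerance = 2e-4)
  expect_equal(power_exact(grid_effect(0.3), predictor_spec(0, 1), 76)$power,
               0.9030, tolerance = 1e-4)
  expect_equal(power_exact(effect_spec(c(1, 2), c(1, 2), 1),
                           predictor_spec(0, 1), 30)$power, 0.05,
               tolerance = 1e-6)
  expect_error(power_exact(fetal_effect(),
                           predictor_spec(24.2, 6, family = "exponential"),
                           173),
               class = "jointpwr_unsupported_error")
})

test_that("exact power reports quadrature diagnostics within tolerance", {
  r <- power_exact(fetal_effect(), fetal_predictor(), 173)
  expect_lte(r$quadrature_diagnostics$abs_error, 1e-8)
  expect_identical(r$numerator_df, 2L)
  expect_identical(r$denominator_df, 171L)
  # an unreachable tolerance must raise a convergence error, never a silent answer
  expect_error(
    power_exact(fetal_effect(), fetal_predictor(), 173,
                quad = quadrature_spec("monte_carlo", node_counts = 100,
                                       absolute_tolerance = 1e-6)),
    class = "jointpwr_convergence_error")
})

stress_grid <- expand.grid(d = c(0.1, 0.3, 0.5), mu = c(0, 0.5, 1),
                           sx2 = c(0.5, 1, 2), n = c(20, 50, 100, 200))

test_that("approximate power never exceeds exact power, strictly when d > 0", {
  for (i in seq_len(nrow(stress_grid))) {
    g <- stress_grid[i, ]
    eff <- grid_effect(g$d)
    prd <- predictor_spec(g$mu, g$sx2)
    pe <- power_exact(eff, prd, g$n)$power
    pa <- power_approx(eff, prd, g$n)$power
    # beta_SD != 0 and sigma2_X > 0 throughout the grid, so dominance is
    # strict; at saturation both powers equal 1 to quadrature precision
    if (pe < 1 - 1e-8) expect_lt(pa, pe) else expect_lte(pa, pe + 1e-9)
  }
})

test_that("exact power is monotone in n, |beta_ID|, and predictor variance", {
  for (d in c(0.1, 0.3, 0.5)) for (mu in c(0, 1)) {
    eff <- grid_effect(d)
    pw_n <- vapply(c(20, 50, 100, 200), function(n)
      power_exact(eff, predictor_spec(mu, 1), n)$power, 0.0)
    expect_true(all(diff(pw_n) >= -1e-10))
    pw_v <- vapply(c(0.5, 1, 2), function(v)
      power_exact(eff, predictor_spec(mu, v), 50)$power, 0.0)
    expect_true(all(diff(pw_v) >= -1e-10))
  }
  # growing intercept difference with the sign structure held fixed
  pw_b <- vapply(c(0.1, 0.3, 0.5, 0.8), function(b)
    power_exact(effect_spec(c(b, 1.3), c(0, 1), 1),
                predictor_spec(0.5, 1), 50)$power, 0.0)
  expect_true(all(diff(pw_b) > 0))
})

test_that("degenerate d = 0 collapses exact power onto the approximation", {
  eff <- effect_spec(c(0.4, 1), c(0, 1), 1)  # slope difference zero
  for (n in c(20, 100)) {
    pe <- power_exact(eff, predictor_spec(0.7, 2), n)
    pa <- power_approx(eff, predictor_spec(0.7, 2), n)
    expect_equal(pe$power, pa$power, tolerance = 1e-10)
    expect_identical(pe$quadrature_diagnostics$scheme, "degenerate")
  }
})

test_that("general-p path at p = 1 equals the scalar simple-regression path", {
  for (i in c(1, 14, 55, 100)) {
    g <- stress_grid[i, ]
    pe <- power_exact(grid_effect(g$d), predictor_spec(g$mu, g$sx2), g$n)$power
    ps <- power_exact_simple(g$d, g$d, 1, g$mu, g$sx2, g$n)$power
    expect_equal(pe, ps, tolerance = 1e-10)
  }
  pe <- power_exact(fetal_effect(), fetal_predictor(), 173)$power
  ps <- power_exact_simple(-0.098, 0.007, 0.095, 24.2, 6, 173)$power
  expect_equal(pe, ps, tolerance = 1e-10)
})

test_that("1-D mixture and 2-D Hermite-x-chisq quadratures agree to 1e-7", {
  q2 <- quadrature_spec("hermite_x_chisq_2d")
  for (i in seq_len(nrow(stress_grid))) {
    g <- stress_grid[i, ]
    eff <- grid_effect(g$d)
    prd <- predictor_spec(g$mu, g$sx2)
    expect_equal(power_exact(eff, prd, g$n)$power,
                 power_exact(eff, prd, g$n, quad = q2)$power,
                 tolerance = 1e-7)
  }
})

test_that("mixing-variable Monte Carlo scheme agrees with the quadratures", {
  set.seed(5)
  qmc <- quadrature_spec("monte_carlo", node_counts = 400000)
  pe <- power_exact(grid_effect(0.3), predictor_spec(0.5, 1), 48)$power
  pm <- power_exact(grid_effect(0.3), predictor_spec(0.5, 1), 48,
                    quad = qmc)$power
  expect_equal(pm, pe, tolerance = 5e-3)
})

test_that("exact power matches full data-level Monte Carlo on five configurations", {
  configs <- list(
    list(beta = c(0.3, 1.3), theta = c(0, 1), s2 = 1, mu = 0, sx2 = 0.5, n = 99),
    list(beta = c(0.3, 1.3), theta = c(0, 1), s2 = 1, mu = 1, sx2 = 2, n = 28),
    list(beta = c(0.4, 1.4), theta = c(0, 1), s2 = 1, mu = 0.5, sx2 = 1, n = 30),
    list(beta = c(0.5, 1.5), theta = c(0, 1), s2 = 1, mu = 0, sx2 = 2, n = 20),
    list(beta = c(4.1, 0.15), theta = c(4.198, 0.143), s2 = 0.095,
         mu = 24.2, sx2 = 6, n = 173))
  R <- 200000
  for (k in seq_along(configs)) {
    cf <- configs[[k]]
    pe <- power_exact(effect_spec(cf$beta, cf$theta, cf$s2),
                      predictor_spec(cf$mu, cf$sx2), cf$n)$power
    emp <- oracle_mc_power(cf$beta, cf$theta, cf$s2, cf$n, 0.05, R,
                           seed = 300 + k, mu = cf$mu, sx2 = cf$sx2)
    expect_lt(abs(pe - emp), 3.5 * mc_se(pe, R))
  }
})

test_that("quadrature_spec rejects out-of-contract settings", {
  expect_error(quadrature_spec(absolute_tolerance = 1e-3),
               class = "jointpwr_input_error")
  expect_error(quadrature_spec(tail_mass_cut = 1e-6),
               class = "jointpwr_input_error")
  expect_error(quadrature_spec("monte_carlo", node_counts = 0),
               class = "jointpwr_input_error")
})
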