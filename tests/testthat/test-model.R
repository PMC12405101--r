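p0 <- model_params()

test_that("relative growth follows the power law at its anchor points", {
  expect_equal(relative_growth(1, p0), 1.95)
  # analytic unit-growth biomass: a b^-k = 1 at b = a^(1/k)
  expect_equal(relative_growth(1.95^10, p0), 1, tolerance = 1e-12)
  # absolute growth near the productivity optimum
  expect_equal(300 * (relative_growth(300, p0) - 1), 30.7, tolerance = 0.05)
  expect_error(relative_growth(-5, p0), "non-negative")
})

test_that("plot growth has exactly the analytic roots and maximum", {
  expect_equal(plot_growth(0, p0), 0)
  eq <- p0$growth_coeff^(1 / p0$growth_exp)
  expect_equal(plot_growth(eq, p0), 0, tolerance = 1e-9)
  # the equilibrium rounds to 800 g m^-2
  expect_equal(round(eq, -2), 800)
  # grid-search oracle over the full biomass range
  bb <- seq(0.1, 1000, by = 0.1)
  gg <- plot_growth(bb, p0)
  b_star_oracle <- bb[which.max(gg)]
  b_star <- (p0$growth_coeff * (1 - p0$growth_exp))^(1 / p0$growth_exp)
  expect_equal(b_star, b_star_oracle, tolerance = 0.1)
  expect_equal(max(gg), plot_growth(b_star, p0), tolerance = 1e-4)
  # the maximum rounds to 31 g m^-2, reached near 300 g m^-2
  expect_equal(round(plot_growth(b_star, p0)), 31)
  # no other non-negative roots besides 0 and the equilibrium
  expect_true(all(gg[bb < eq - 0.1] > 0))
  expect_true(all(plot_growth(seq(eq + 1, 2000, 1), p0) < 0))
})

test_that("the landscape factor is a Jensen correction", {
  expect_equal(landscape_factor(rep(250, 50), p0), 1)
  expect_lt(landscape_factor(c(100, 700), p0), 1)
  # direct Monte-Carlo oracle: explicit mean-of-growth over growth-of-mean
  set.seed(5)
  b <- runif(500, 0, 780)
  oracle <- mean(1.95 * b^0.9 - b) /
    (1.95 * mean(b)^0.9 - mean(b))
  expect_equal(landscape_factor(b, p0), oracle, tolerance = 1e-9)
  expect_error(landscape_factor(rep(0, 5), p0), "undefined")
  expect_error(landscape_factor(rep(900, 5), p0), "undefined")
})

test_that("the Jensen bound f <= 1 holds over many random samples", {
  set.seed(6)
  for (i in 1:200) {
    b <- runif(sample(3:50, 1), 0, 750)
    if (mean(b) <= 0 || mean(b) >= 794) next
    f <- landscape_factor(b, p0)
    expect_lte(f, 1 + 1e-12)
  }
  # equality only for homogeneous samples
  expect_lt(landscape_factor(c(10, 500), p0), 1 - 1e-6)
})

test_that("landscape factors interpolate linearly with constant extrapolation", {
  anchors <- tibble::tibble(year = c(1963, 1973), f = c(0.60, 0.70))
  out <- interpolate_factor(anchors, 1960:1975)
  expect_equal(out$f[out$year == 1968], 0.65)
  expect_equal(out$f[out$year == 1960], 0.60)
  expect_equal(out$f[out$year == 1975], 0.70)
  expect_equal(out$provenance[out$year == 1963], "computed")
  expect_equal(out$provenance[out$year == 1968], "interpolated")
  single <- interpolate_factor(tibble::tibble(year = 2000, f = 0.6), 1995:2005)
  expect_true(all(single$f == 0.6))
})

test_that("reindeer-year densities and the intake constant match their worked values", {
  expect_equal(reindeer_year_density(2.3, 1, 157), 0.989, tolerance = 1e-3)
  expect_equal(reindeer_year_density(500, 100, 365), 5)
  expect_equal(reindeer_year_density(500, 100, 0), 0)
  expect_error(reindeer_year_density(10, 1, 400), "365")
  expect_equal(metabolic_intake_constant(20, 10.8, 365), 675.926,
               tolerance = 1e-3)
  expect_equal(round(metabolic_intake_constant()), 676)
  expect_equal(round(metabolic_intake_constant() / 2), 338)
  expect_equal(metabolic_intake_constant(days = 0), 0)
})

test_that("annual losses reproduce the district worked examples", {
  # winter district, 1992: b = 109 g m^-2, l = 0.019, one reindeer-year
  st <- annual_step(109, 1, 0.65, model_params(loss_factor = 0.019))
  expect_equal(st$w, 2.071, tolerance = 1e-9)       # ~2100 kg km^-2
  expect_equal(round(1000 * st$w, -2), 2100)
  st2 <- annual_step(109, 7.3, 0.65, model_params(loss_factor = 0.019))
  expect_equal(st2$w, 15.1187, tolerance = 1e-4)    # ~15,100 kg km^-2
  expect_equal(round(1000 * st2$w, -2), 15100)
  # year-round mixed use: b = 24 g m^-2, l = 0.069
  st3 <- annual_step(24, 1, 0.65, model_params(loss_factor = 0.069))
  expect_equal(st3$w, 1.656, tolerance = 1e-9)      # ~1700 kg km^-2
  expect_equal(round(1000 * st3$w, -2), 1700)
})

test_that("the model variants zero the right fluxes", {
  st <- annual_step(200, 3, 0.7, p0, "full")
  expect_true(all(c(st$g, st$e, st$w) > 0))
  expect_equal(annual_step(200, 3, 0.7, p0, "no_loss")$w, 0)
  io <- annual_step(200, 3, 0.7, p0, "intake_only")
  expect_equal(c(io$g, io$w), c(0, 0))
  expect_gt(io$e, 0)
  expect_equal(annual_step(200, 3, 0.7, p0, "no_intake")$e, 0)
})

test_that("simulation keeps exact mass bookkeeping and clamps at zero", {
  years <- 1946:2020
  dens <- flat_density(years, 4)
  tr <- simulate_biomass(400, years, dens, 0.65, p0)
  free <- !tr$clamped
  expect_equal(tr$b_next[free], (tr$b + tr$g - tr$e - tr$w)[free])
  expect_equal(tr$b[-1], tr$b_next[-nrow(tr)])
  expect_true(all(tr$b >= 0))
  # heavy grazing drives biomass to the floor, with the clamp flagged
  hard <- simulate_biomass(50, years, flat_density(years, 50), 0.65, p0)
  expect_true(any(hard$clamped))
  expect_true(all(hard$b_next >= 0))
  expect_error(simulate_biomass(400, 1940:2020, dens, 0.65, p0), "1940")
})

test_that("without reindeer the biomass converges to the analytic equilibrium", {
  years <- 1:600
  dens <- flat_density(years, 0)
  eq <- p0$growth_coeff^(1 / p0$growth_exp)
  for (b0 in c(50, 400, 700)) {
    tr <- simulate_biomass(b0, years, dens, 1, p0)
    expect_true(all(diff(tr$b) >= -1e-9))          # monotone approach
    expect_equal(tr$b_next[nrow(tr)], eq, tolerance = 1e-3)
  }
  # fixed-point oracle: the equilibrium maps to itself
  expect_equal(annual_step(eq, 0, 1, p0)$b_next, eq, tolerance = 1e-9)
})

test_that("cumulative-intake-only runs decline steadily to the floor", {
  years <- 1:120
  tr <- simulate_biomass(400, years, flat_density(years, 6), 0.65, p0,
                         "intake_only")
  pre_floor <- tr$b_next > 0
  expect_true(all(diff(tr$b[pre_floor]) < 0))
  expect_equal(tr$b_next[nrow(tr)], 0)
})

test_that("the no-loss steady state balances growth against intake", {
  years <- 1:800
  d <- 2; f <- 0.65
  tr <- simulate_biomass(400, years, flat_density(years, d), f, p0, "no_loss")
  b_star <- tr$b_next[nrow(tr)]
  # root-finding oracle for f * growth(b) = i d on the declining branch
  root <- uniroot(function(b) f * plot_growth(b, p0) -
                    p0$intake_t_per_reindeer_year * d,
                  c(300, 794))$root
  expect_equal(b_star, root, tolerance = 0.5)
  # approaching the upper equilibrium from below intake pressure
  expect_gt(b_star, 600)
})

test_that("loss fitting recovers the generating parameter exactly when noiseless", {
  years <- 1946:2020
  dens <- flat_density(years, 3)
  fts <- flat_ft(years, 0.65)
  for (l_true in c(0.019, 0.069)) {
    p <- model_params(loss_factor = l_true)
    obs <- forward_reconstruction_series(p, dens, fts, 400, 0,
                                         seq(1950, 2020, 10))
    fit <- fit_loss_parameter(obs, 400, dens, fts, p)
    expect_equal(fit$l_hat, l_true, tolerance = 1e-4)
  }
  # a loss-free history gives the boundary optimum l = 0
  p_free <- model_params(loss_factor = 0)
  obs0 <- forward_reconstruction_series(p_free, dens, fts, 400, 0,
                                        seq(1950, 2020, 10))
  fit0 <- fit_loss_parameter(obs0, 400, dens, fts, p_free)
  expect_equal(fit0$l_hat, 0, tolerance = 1e-6)
  expect_error(fit_loss_parameter(obs0[1, ], 400, dens, fts, p_free),
               ">= 2")
})

test_that("winter-only and year-round grazing regimes keep their loss ordering", {
  years <- 1946:2020
  fts <- flat_ft(years, 0.65)
  dens_wi <- flat_density(years, 5 * 157 / 365)   # winter-only occupancy
  dens_yr <- flat_density(years, 3)               # year-round presence
  obs_wi <- forward_reconstruction_series(
    model_params(loss_factor = 0.019), dens_wi, fts, 600, 0.05,
    seq(1950, 2020, 10), seed = 21)
  obs_yr <- forward_reconstruction_series(
    model_params(intake_t_per_reindeer_year = 0.338, loss_factor = 0.069),
    dens_yr, fts, 300, 0.05, seq(1950, 2020, 10), seed = 22)
  fit_wi <- fit_loss_parameter(obs_wi, 600, dens_wi, fts, model_params())
  fit_yr <- fit_loss_parameter(obs_yr, 300, dens_yr, fts,
                               model_params(intake_t_per_reindeer_year = 0.338))
  expect_lt(fit_wi$l_hat, fit_yr$l_hat)
})

test_that("trajectories from different initial biomasses contract together", {
  years <- 1946:2020
  dens <- flat_density(years, 3)
  runs <- purrr::map_dbl(c(200, 400, 600), function(b0) {
    tr <- simulate_biomass(b0, years, dens, 0.65, p0)
    tr$b[tr$year == 1976]
  })
  spread30 <- diff(range(runs))
  expect_lt(spread30, 0.25 * 400)
})

test_that("per-reindeer loss-to-intake ratios scale linearly with biomass", {
  p <- model_params(loss_factor = 0.019)
  tr <- simulate_biomass(100, 2000:2002, flat_density(2000:2002, 0), 1, p)
  r <- loss_to_intake_ratio(tr, p)
  expect_equal(r$loss_intake_ratio[1], 100 * 0.019 / 0.676, tolerance = 1e-9)
  expect_equal(round(r$loss_intake_ratio[1], 2), 2.81)
  # b l = i gives ratio one
  tr2 <- simulate_biomass(0.676 / 0.019, 2000:2002,
                          flat_density(2000:2002, 0), 1, p)
  expect_equal(loss_to_intake_ratio(tr2, p)$loss_intake_ratio[1], 1,
               tolerance = 1e-9)
  # linearity in b
  expect_equal(r$loss_intake_ratio / r$b, rep(0.019 / 0.676, 3),
               tolerance = 1e-9)
})
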