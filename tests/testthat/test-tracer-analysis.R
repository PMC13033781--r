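make_line_ts <- function(slope = -2, intercept = 10, days = 0:5,
                         species = "N2O_46") {
  # partial pressures chosen so the converted ug-N amounts follow the line
  vial <- vial_config()
  K0 <- henry_constant_n2o(vial$temperature)
  alpha <- 0.070 / (0.082057366 * 298.15) * 1e6
  beta <- K0 * 0.030 * 1e6
  per_atm <- if (species == "N2O_46") alpha + beta else alpha
  amount <- intercept + slope * days
  data.frame(vial_id = "t", run = "t", replicate = 1L, day = days,
             variable = species, value = amount / (per_atm * 28),
             unit = "atm")
}

test_that("an exact line is recovered with r squared 1", {
  ts <- make_line_ts(slope = -2, intercept = 10)
  est <- fit_consumption_rate(ts, biomass = 1)
  expect_equal(est$slope, -2, tolerance = 1e-10)
  expect_equal(est$intercept, 10, tolerance = 1e-10)
  expect_equal(est$r_squared, 1, tolerance = 1e-9)
  expect_equal(est$specific_rate, 2, tolerance = 1e-10)
  expect_equal(est$n_points, 6)
})

test_that("rate fitting validates window and biomass", {
  ts <- make_line_ts()
  expect_error(fit_consumption_rate(ts, window = c(2, 2), biomass = 1),
               "two sampling days")
  expect_error(fit_consumption_rate(ts, biomass = 0), "positive")
  expect_error(fit_consumption_rate(ts, biomass = -1), "positive")
})

test_that("round-trip recovery of configured first-order rates", {
  # noise-free simulate -> fit recovers the scenario's effective rate
  sc <- tiny_first_order(k_red = 2e4, B0 = 5e-4, days = 0:8)
  ts <- simulate_incubation(sc)
  est <- fit_consumption_rate(ts, biomass = sc$initial_biomass)
  expect_equal(est$specific_rate, 28 * sc$k_red * mean_p46(ts),
               tolerance = 0.01)

  # with noise: recovered within 3 SE over 100 seeds
  rates <- vapply(1:100, function(s) {
    scn <- tiny_first_order(k_red = 2e4, B0 = 5e-4, days = 0:8, seed = s,
                            noise = c(N2O_46 = 2e-6))
    m <- measure_timeseries(ts, scn)
    fit_consumption_rate(m, biomass = scn$initial_biomass)$specific_rate
  }, 1)
  truth <- est$specific_rate
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - truth), 3 * se + 1e-9)
})

test_that("percent_slowdown reproduces the rate comparison and is scale-free", {
  expect_equal(percent_slowdown(48.7, 127), 61.65, tolerance = 1e-3)
  expect_equal(round(percent_slowdown(48.7, 127)), 62)
  expect_equal(percent_slowdown(5, 5), 0)
  expect_equal(percent_slowdown(0, 5), 100)
  expect_error(percent_slowdown(1, 0), "positive")
  set.seed(2)
  for (i in 1:10) {
    a <- runif(1); b <- runif(1, 0.1, 2); c <- runif(1, 0.1, 10)
    expect_equal(percent_slowdown(a, b), percent_slowdown(c * a, c * b),
                 tolerance = 1e-10)
  }
})

test_that("cumulative_retardation compares consumed pools", {
  ts <- make_line_ts(slope = -1, intercept = 10)
  expect_equal(cumulative_retardation(ts, ts, day = 5), 0)
  flat <- make_line_ts(slope = 0, intercept = 10)
  expect_equal(cumulative_retardation(flat, ts, day = 5), 100)
  expect_error(cumulative_retardation(ts, flat, day = 5),
               "no net consumption")
  expect_error(cumulative_retardation(ts, ts, day = 99), "cover day")
})

test_that("acetylene-reduction conversion applies the 3:1 stoichiometry", {
  expect_equal(ara_to_fixation(3), 28)
  expect_equal(ara_to_fixation(0), 0)
  expect_equal(ara_to_fixation(2636), 2636 / 3 * 28, tolerance = 1e-12)
  expect_equal(ara_to_fixation(2636), 2.46e4, tolerance = 1e-3)
  expect_error(ara_to_fixation(-1), ">= 0")
  # linearity and inverse round-trip
  set.seed(4)
  r <- runif(5, 0, 1e4)
  expect_equal(ara_to_fixation(2 * r), 2 * ara_to_fixation(r))
  expect_equal(ara_to_fixation(r) / 28 * 3, r, tolerance = 1e-12)
})

test_that("fixation_fraction reproduces the printed rate ratios", {
  expect_equal(fixation_fraction(48.7, 24600), 0.198, tolerance = 1e-3)
  expect_equal(round(fixation_fraction(48.7, 24600), 2), 0.20)
  expect_equal(round(fixation_fraction(127, 24600), 2), 0.52)
  expect_equal(fixation_fraction(0, 10), 0)
  expect_error(fixation_fraction(1, 0), "positive")
  expect_equal(fixation_fraction(3 * 48.7, 3 * 24600),
               fixation_fraction(48.7, 24600), tolerance = 1e-12)
})

test_that("per-cell rates convert through the 0.28 pg cell mass", {
  expect_equal(per_cell_to_specific(1), 1e-15 / 0.28e-12 * 1e6,
               tolerance = 1e-12)
  expect_equal(per_cell_to_specific(1), 3.57e3, tolerance = 1e-3)
  expect_equal(per_cell_to_specific(0), 0)
  expect_equal(per_cell_to_specific(1, 0.56), per_cell_to_specific(1) / 2)
  expect_error(per_cell_to_specific(1, 0), "positive")
})

test_that("close_budget partitions an exactly accounted tracer", {
  # constructed series: consumed 10 ug-N, emitted 6 ug-N, fixed 4 ug-N
  vial <- vial_config()
  K0 <- henry_constant_n2o(vial$temperature)
  alpha <- 0.070 / (0.082057366 * 298.15) * 1e6
  beta <- K0 * 0.030 * 1e6
  two <- data.frame(
    vial_id = "t", run = "t", replicate = 1L,
    day = rep(c(0, 10), each = 2),
    variable = rep(c("N2O_46", "N2_30"), 2),
    value = c(12 / (28 * (alpha + beta)), 0,
              2 / (28 * (alpha + beta)), 6 / (28 * alpha)),
    unit = "atm")
  nat <- natural_abundance_15N()
  # biomass pool holding exactly 4 ug tracer-derived N over 100 ug at baseline
  pool <- isotope_pool(104, (100 * nat + 4) / 104)
  b <- close_budget(two, pool)
  expect_equal(b$consumed_N2O, 10, tolerance = 1e-9)
  expect_equal(b$emitted_30N2, 6, tolerance = 1e-9)
  expect_equal(b$fixed_15N_excess, 4, tolerance = 1e-9)
  expect_equal(b$closure, 100, tolerance = 1e-9)
  expect_equal(b$missing, 0, tolerance = 1e-9)
  expect_equal(b$flag, "ok")
})

test_that("sink-free bias-free noise-free simulations close at exactly 100%", {
  sc <- tiny_first_order(k_red = 3e4, B0 = 1e-3, days = 0:8)
  ts <- simulate_incubation(sc)
  b <- close_budget(ts)
  expect_equal(b$closure, 100, tolerance = 1e-9)

  # and with re-fixation of the emitted 30N2 (full two-step chain)
  sc2 <- update_scenario(sc, Vmax_fix = 600, growth_rate = 0.05)
  b2 <- close_budget(simulate_incubation(sc2))
  expect_equal(b2$closure, 100, tolerance = 1e-8)
})

test_that("a blank incubation is flagged as having no net consumption", {
  sc <- update_scenario(tiny_first_order(), initial_biomass = 0)
  b <- close_budget(simulate_incubation(sc))
  expect_equal(b$flag, "no net consumption")
  expect_true(is.na(b$closure))
})
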