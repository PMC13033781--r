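test_that("without biomass every gas pool is constant", {
  sc <- update_scenario(tiny_first_order(), initial_biomass = 0)
  ts <- simulate_incubation(sc)
  for (v in c("N2O_46", "N2_30", "O2")) {
    vals <- ts$value[ts$variable == v]
    expect_equal(max(vals) - min(vals), 0)
  }
  expect_equal(unique(ts$value[ts$variable == "N2_30"]), 0)
})

test_that("15N and 14N are conserved through the full transfer chain", {
  scn <- packaged_scenarios(noise = FALSE)
  for (name in c("RunA", "RunB", "ARA")) {
    tot <- isotope_totals(simulate_incubation(scn[[name]]))
    expect_lt(diff(range(tot$total_15N)) / max(tot$total_15N), 1e-6)
    expect_lt(diff(range(tot$total_14N)) / max(tot$total_14N), 1e-6)
  }
  # with an unmeasured sink the ledger still balances (label parked there)
  tot <- isotope_totals(simulate_incubation(tiny_first_order(sink = 0.3)))
  expect_lt(diff(range(tot$total_15N)) / max(tot$total_15N), 1e-6)
})

test_that("state variables stay nonnegative in noise-free runs", {
  scn <- packaged_scenarios(noise = FALSE)
  for (name in c("RunA", "RunB", "ARA")) {
    ts <- simulate_incubation(scn[[name]])
    expect_true(all(ts$value[ts$variable != "atom15"] >= 0))
  }
})

test_that("ambient N2 competitively suppresses the N2O reduction rate", {
  p28 <- c(0, 0.2, 0.5, 0.8)
  drop1 <- vapply(p28, function(p) {
    ts <- simulate_incubation(tiny_mm(p_n2 = p))
    p46 <- ts$value[ts$variable == "N2O_46"]
    p46[1] - p46[2]  # day-0 -> day-1 consumption
  }, 1)
  expect_true(all(diff(drop1) < 0))
})

test_that("linear fits recover the configured first-order rate", {
  # shallow decline, constant biomass: specific rate ~ 28 * k_red * <p46>
  sc <- tiny_first_order(k_red = 1e4, B0 = 2e-4, days = 0:6)
  ts <- simulate_incubation(sc)
  est <- fit_consumption_rate(ts, biomass = sc$initial_biomass)
  expect_equal(est$specific_rate, 28 * sc$k_red * mean_p46(ts),
               tolerance = 0.01)
  expect_gt(est$r_squared, 0.999)
})

test_that("closed-form exponential decay is reproduced at constant biomass", {
  sc <- tiny_first_order(k_red = 5e4, B0 = 1e-3, days = 0:10)
  ts <- simulate_incubation(sc)
  vial <- sc$vial
  K0 <- henry_constant_n2o(vial$temperature)
  alpha <- 0.070 / (0.082057366 * 298.15) * 1e6
  beta <- K0 * 0.030 * 1e6
  lambda <- sc$k_red * sc$initial_biomass / (alpha + beta)
  p <- ts$value[ts$variable == "N2O_46"]
  days <- ts$day[ts$variable == "N2O_46"]
  expect_equal(p, p[1] * exp(-lambda * days), tolerance = 1e-6)
})

test_that("the measurement model honours its seeding contract", {
  sc <- tiny_first_order(noise = c(N2O_46 = 2e-6, atom15 = 5e-5), seed = 42)
  ts <- simulate_incubation(sc)

  m1 <- measure_timeseries(ts, sc)
  m2 <- measure_timeseries(ts, sc)
  expect_identical(m1, m2)
  expect_equal(sort(unique(m1$replicate)), 1:3)

  m3 <- measure_timeseries(ts, update_scenario(sc, seed = 43))
  expect_false(identical(m1$value, m3$value))

  clean <- measure_timeseries(ts, tiny_first_order(seed = 42))
  truth <- ts[!(ts$variable %in% c("sink_N", "dissolved_N2O_46")), ]
  for (r in 1:3) {
    expect_equal(clean$value[clean$replicate == r], truth$value)
  }
})

test_that("replicate noise averages out at the law-of-large-numbers rate", {
  sc <- update_scenario(tiny_first_order(noise = c(N2O_46 = 2e-6), seed = 7),
                        initial_biomass = 0, replicates = 1000)
  m <- measure_timeseries(simulate_incubation(sc), sc)
  p0 <- 0.01 / 100.1  # constant truth: the spiked level
  obs <- m$value[m$variable == "N2O_46" & m$day == 0]
  se <- 2e-6 / sqrt(length(obs))
  expect_lt(abs(mean(obs) - p0), 3 * se)
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(run_scenario(k_red = -1), ">= 0")
  expect_error(run_scenario(sink_fraction = 1), "sink_fraction")
  expect_error(run_scenario(replicates = 0), "replicates")
  expect_error(run_scenario(step = 0.5), "step")
  expect_error(run_scenario(noise_sd = c(1, 2)), "named")
  expect_error(
    simulate_incubation(run_scenario(rate_law_mode = "competitive_MM",
                                     Vmax_red = 1, initial_biomass = 1e-3)),
    "K_N2O")
})

test_that("packaged scenarios encode the documented study conditions", {
  scn <- packaged_scenarios()
  gA <- scn$RunA$initial_gas
  expect_equal(unname(gA[["N2_28"]]), 0.95, tolerance = 0.01)
  expect_equal(unname(gA[["N2O_46"]]) * 1e6, 100, tolerance = 1)
  gB <- scn$RunB$initial_gas
  expect_equal(unname(gB[["He"]]), 0.95, tolerance = 0.01)
  expect_equal(unname(scn$ARA$initial_gas[["C2H2"]]), 0.10, tolerance = 1e-6)
  expect_equal(scn$RunC_blank$initial_biomass, 0)
  expect_length(scn$O2_series, 4)
  expect_equal(vapply(scn$O2_series, function(s)
    unname(s$initial_gas[["O2"]]), 1),
    c(O2_run1 = 0, O2_run2 = 0.05, O2_run3 = 0.20, O2_run4 = 0.30),
    tolerance = 0.01)

  # blank run: tracer untouched, no 30N2
  ts <- simulate_incubation(scn$RunC_blank)
  expect_equal(diff(range(ts$value[ts$variable == "N2O_46"])), 0)
  expect_equal(max(ts$value[ts$variable == "N2_30"]), 0)
})

test_that("O2 inhibition slows N2O uptake in the O2 series", {
  scn <- packaged_scenarios(noise = FALSE)
  consumed <- vapply(scn$O2_series, function(s) {
    ts <- simulate_incubation(s)
    p <- ts$value[ts$variable == "N2O_46"]
    p[1] - p[length(p)]
  }, 1)
  expect_true(all(diff(consumed) < 0))
})
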