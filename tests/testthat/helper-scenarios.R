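# small fast scenarios used across tests

# constant-biomass first-order consumer: decline stays shallow so the
# linear fit tracks k_red * <p46> closely
tiny_first_order <- function(k_red = 1e4, days = 0:6, B0 = 1e-3,
                             sink = 0, seed = 1L, noise = numeric(0)) {
  run_scenario(
    label = "tiny", initial_biomass = B0, growth_rate = 0,
    k_red = k_red, sink_fraction = sink,
    initial_gas = apply_spike(gas_state(He = 0.95, CO2 = 0.05),
                              100, 0.1, 0.10, "N2O_46"),
    noise_sd = noise, sampling_days = days, seed = seed)
}

# competitive Michaelis-Menten scenario with ambient N2
tiny_mm <- function(p_n2 = 0.5, Vmax_red = 50, K_N2O = 5e-4, days = 0:4) {
  base <- gas_state(He = 0.95 - p_n2, N2_28 = p_n2, CO2 = 0.05)
  run_scenario(
    label = "mm", initial_biomass = 1e-3,
    rate_law_mode = "competitive_MM", Vmax_red = Vmax_red, K_N2O = K_N2O,
    initial_gas = apply_spike(base, 100, 0.1, 0.10, "N2O_46"),
    sampling_days = days)
}

mean_p46 <- function(ts, window = range(ts$day)) {
  sub <- ts[ts$variable == "N2O_46" & ts$day >= window[1] &
              ts$day <= window[2], ]
  mean(tapply(sub$value, sub$day, mean))
}
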