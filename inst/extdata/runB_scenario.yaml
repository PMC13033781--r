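schema_version: 1
label: RunB
initial_biomass: 0.002
biomass_N_frac: 0.1
growth_rate: 0.06
light_duty_cycle: 0.5
rate_law_mode: empirical_first_order
k_red: 101272.53565360000357
Vmax_red: 0.0
K_N2O: .na.real
Km_N2: 0.04
Ks_C2H2: 0.005
Vmax_fix: 880.0
Vmax_eth: 2640.0
O2_yield: 37500.0
O2_inhibition_K: .na.real
sink_fraction: 0.26
atom15_bias: 0.0
replicates: 3
seed: 1
step: 0.01
vial:
  total_volume: 100.0
  liquid_volume: 30.0
  temperature: 298.149999999999977
  pressure: 1.0
  nominal_volume: 100.0
initial_gas:
  He: 0.94995004995005
  CO2: 0.04995004995005
  N2O_46: 9.990009990009993e-05
noise_sd:
  N2O_46: 0.0
  N2_30: 0.0
  N2_28: 0.0
  O2: 0.0
  CO2: 0.0
  C2H2: 0.0
  C2H4: 0.0
  He: 0.0
  N2O_44: 0.0
  biomass: 0.0
  biomass_N: 0.0
  atom15: 0.0
sampling_days:
- 0.0
- 3.0
- 5.0
- 7.0
- 10.0
- 12.0
- 14.0
- 17.0
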