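#' Parameterization of one simulated incubation
#'
#' Everything needed to forward-simulate a closed-vial incubation:
#' geometry, initial headspace, inoculum, growth, the N2O-reduction and
#' nitrogen-fixation rate laws, gas-liquid partitioning, the unmeasured
#' sink, and the measurement model (noise, bias, replication, seed).
#'
#' Two rate-law modes are available for N2O consumption:
#' \describe{
#'   \item{`empirical_first_order`}{`v_red = k_red * p46` (umol per g dry
#'     biomass per day), the effective first-order law used by the packaged
#'     run scenarios.}
#'   \item{`competitive_MM`}{`v_red = Vmax_red * p46 / (K_N2O * (1 +
#'     p28/Km_N2) + p46)`, competitive Michaelis-Menten against ambient N2;
#'     `K_N2O` must be supplied by the user (it is an exploratory mode: the
#'     half-saturation of nitrogenase for N2O has not been measured).}
#' }
#' Nitrogen fixation follows `v_fix = Vmax_fix * pN2 / (Km_N2 * (1 +
#' p46/K_N2O) + pN2)` (the inhibition term is dropped when `K_N2O` is
#' `NA`). When acetylene is present, ethylene production
#' `v = Vmax_eth * pC2H2 / (Ks_C2H2 + pC2H2)` replaces nitrogen fixation,
#' which acetylene suppresses.
#'
#' @param label Run label used in output tables.
#' @param vial A [vial_config()].
#' @param initial_gas A [gas_state()].
#' @param initial_biomass Inoculum dry mass, g.
#' @param biomass_N_frac Nitrogen content of dry biomass (g N / g dry),
#'   used to initialise the biomass nitrogen pool at natural abundance.
#' @param growth_rate Specific growth rate under illumination, day^-1.
#' @param light_duty_cycle Fraction of the day with light (12 h light:dark
#'   cycle = 0.5); multiplies the growth rate.
#' @param rate_law_mode `"empirical_first_order"` or `"competitive_MM"`.
#' @param k_red Effective N2O consumption constant, umol g^-1 day^-1 atm^-1
#'   (empirical mode).
#' @param Vmax_red,K_N2O Michaelis-Menten parameters for N2O reduction
#'   (umol g^-1 day^-1; atm). `K_N2O` has no literature value and defaults
#'   to `NA`.
#' @param Km_N2 Nitrogenase half-saturation for N2, atm (0.04).
#' @param Ks_C2H2 Nitrogenase half-saturation for acetylene, atm (0.005).
#' @param Vmax_fix Maximal N2 fixation rate, umol N2 g^-1 day^-1.
#' @param Vmax_eth Maximal ethylene production rate under acetylene,
#'   umol C2H4 g^-1 day^-1; defaults to `3 * Vmax_fix` (3:1 stoichiometry).
#' @param O2_yield O2 released per unit biomass grown, umol g^-1.
#' @param O2_inhibition_K Optional O2 inhibition constant for N2O uptake,
#'   atm; `NA` (default) disables the factor `1/(1 + pO2/K)`.
#' @param sink_fraction Fraction of reduced N2O routed to an unmeasured
#'   pool (bypassing both 30N2 and biomass), in \[0, 1).
#' @param atom15_bias Additive measurement bias on the biomass atom-15N
#'   channel (models over-closure from imperfect biomass-N measurements).
#' @param noise_sd Named numeric vector of per-channel Gaussian noise SDs
#'   (same units as the channel); missing channels are noise-free.
#' @param sampling_days Days at which measurements are taken.
#' @param replicates Number of replicate vials measured (default 3).
#' @param seed Integer seed for the measurement model.
#' @param step ODE integration step, day (fixed-step RK4; <= 0.01).
#'
#' @return An object of class `run_scenario`.
#' @export
run_scenario <- function(label = "run",
                         vial = vial_config(),
                         initial_gas = gas_state(He = 0.95, CO2 = 0.05),
                         initial_biomass = 0,
                         biomass_N_frac = 0.10,
                         growth_rate = 0,
                         light_duty_cycle = 0.5,
                         rate_law_mode = c("empirical_first_order",
                                           "competitive_MM"),
                         k_red = 0,
                         Vmax_red = 0, K_N2O = NA_real_,
                         Km_N2 = 0.04, Ks_C2H2 = 0.005,
                         Vmax_fix = 0, Vmax_eth = 3 * Vmax_fix,
                         O2_yield = 37500,
                         O2_inhibition_K = NA_real_,
                         sink_fraction = 0,
                         atom15_bias = 0,
                         noise_sd = numeric(0),
                         sampling_days = 0:17,
                         replicates = 3,
                         seed = 1L,
                         step = 0.01) {
  rate_law_mode <- match.arg(rate_law_mode)
  stopifnot(inherits(vial, "vial_config"), inherits(initial_gas, "gas_state"))
  rates <- c(k_red = k_red, Vmax_red = Vmax_red, Km_N2 = Km_N2,
             Ks_C2H2 = Ks_C2H2, Vmax_fix = Vmax_fix, Vmax_eth = Vmax_eth,
             growth_rate = growth_rate, O2_yield = O2_yield)
  if (any(rates < 0, na.rm = TRUE)) {
    stop("rate constants must be >= 0", call. = FALSE)
  }
  if (sink_fraction < 0 || sink_fraction >= 1) {
    stop("sink_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (initial_biomass < 0) stop("initial_biomass must be >= 0", call. = FALSE)
  if (light_duty_cycle < 0 || light_duty_cycle > 1) {
    stop("light_duty_cycle must lie in [0, 1]", call. = FALSE)
  }
  if (step <= 0 || step > 0.01) {
    stop("integration step must be positive and <= 0.01 day", call. = FALSE)
  }
  if (length(sampling_days) < 1 || any(diff(sort(sampling_days)) == 0)) {
    stop("sampling_days must be distinct", call. = FALSE)
  }
  if (length(noise_sd) > 0 && (is.null(names(noise_sd)) || any(noise_sd < 0))) {
    stop("noise_sd must be a named vector of nonnegative SDs", call. = FALSE)
  }
  structure(
    list(label = label, vial = vial, initial_gas = initial_gas,
         initial_biomass = initial_biomass, biomass_N_frac = biomass_N_frac,
         growth_rate = growth_rate, light_duty_cycle = light_duty_cycle,
         rate_law_mode = rate_law_mode, k_red = k_red, Vmax_red = Vmax_red,
         K_N2O = K_N2O, Km_N2 = Km_N2, Ks_C2H2 = Ks_C2H2,
         Vmax_fix = Vmax_fix, Vmax_eth = Vmax_eth, O2_yield = O2_yield,
         O2_inhibition_K = O2_inhibition_K, sink_fraction = sink_fraction,
         atom15_bias = atom15_bias, noise_sd = noise_sd,
         sampling_days = sort(sampling_days), replicates = as.integer(replicates),
         seed = as.integer(seed), step = step),
    class = "run_scenario")
}

#' @export
print.run_scenario <- function(x, ...) {
  cat(sprintf(
    "<run_scenario> '%s': %s, B0 = %.3g g, %d replicate(s), days %g-%g, seed %d\n",
    x$label, x$rate_law_mode, x$initial_biomass, x$replicates,
    min(x$sampling_days), max(x$sampling_days), x$seed))
  invisible(x)
}

#' Modify a scenario
#'
#' Returns a copy of `scenario` with the named fields replaced, re-running
#' all validity checks.
#'
#' @param scenario A [run_scenario()].
#' @param ... Fields to replace (any argument of [run_scenario()]).
#' @return A [run_scenario()].
#' @export
update_scenario <- function(scenario, ...) {
  stopifnot(inherits(scenario, "run_scenario"))
  fields <- unclass(scenario)
  fields[names(list(...))] <- list(...)
  do.call(run_scenario, fields)
}

# calibrated effective parameters of the packaged study scenarios; see the
# methods vignette for the calibration procedure
.CAL <- list(
  k_red_A    = 2.663484214908e4,   # umol g^-1 day^-1 atm^-1
  k_red_B    = 1.012725356536e5,
  Vmax_eth_ARA = 5.464025123734e3, # umol C2H4 g^-1 day^-1
  sink_B     = 0.26,
  bias_A     = 3.106740430309e-3,  # additive atom-fraction bias
  B0_AB      = 2.0e-3,             # g dry inoculum, Runs A/B
  B0_ARA     = 2.0e-4,             # g dry inoculum, ARA vials
  mu_A       = 0.06500855,         # day^-1 under light
  mu_B       = 0.06,
  mu_ARA     = 0.25,
  Vmax_fix_A = 40,                 # umol N2 g^-1 day^-1
  Vmax_fix_B = 880                 # N-starved vials: full nitrogenase capacity
)

# default instrument noise (channel units): GC gas channels in atm,
# biomass channels in their own units
.DEFAULT_NOISE <- c(
  N2O_46 = 2e-6, N2_30 = 2e-6, N2_28 = 2e-3, O2 = 2e-3, CO2 = 1e-3,
  C2H2 = 1e-3, C2H4 = 2e-5, He = 0, N2O_44 = 2e-6,
  biomass = 1e-4, biomass_N = 5, atom15 = 5e-5
)

#' Packaged incubation scenarios
#'
#' The calibrated scenarios of the study design: `RunA` (N2-based headspace,
#' 95 mL N2 + 5 mL CO2 + 100 ppm 46N2O), `RunB` (He-based, 95 mL He + 5 mL
#' CO2 + 100 ppm 46N2O), `RunC_blank` (as B but without biomass), `ARA`
#' (acetylene-reduction assay, 85 mL He + 5 mL CO2 + 10 mL C2H2), and
#' `O2_series` (four vials at 0/5/20/30 % O2 with 100 ppm 46N2O). Effective
#' rate constants, the Run B sink fraction and the Run A atom-fraction bias
#' are calibrated so that the analysis pipeline applied to noise-free
#' simulations reproduces the study's summary numbers (specific consumption
#' rates, budget closures, day-17 retardation).
#'
#' @param seed Integer seed stored in each scenario's measurement model.
#' @param noise If `FALSE`, instrument noise SDs are zeroed (the additive
#'   atom-fraction bias of Run A is retained: it is a systematic error, not
#'   noise).
#'
#' @return Named list of [run_scenario()] objects.
#' @export
#' @examples
#' names(packaged_scenarios())
packaged_scenarios <- function(seed = 1L, noise = TRUE) {
  nsd <- if (noise) .DEFAULT_NOISE else .DEFAULT_NOISE * 0
  vial <- vial_config()
  spike <- function(base) apply_spike(base, vial$nominal_volume, 0.1, 0.10,
                                      "N2O_46")
  days_ab <- c(0, 3, 5, 7, 10, 12, 14, 17)
  base_A <- mixture_from_volumes(c(N2_28 = 95, CO2 = 5))
  base_B <- mixture_from_volumes(c(He = 95, CO2 = 5))

  runA <- run_scenario(
    label = "RunA", vial = vial, initial_gas = spike(base_A),
    initial_biomass = .CAL$B0_AB, growth_rate = .CAL$mu_A,
    k_red = .CAL$k_red_A, Vmax_fix = .CAL$Vmax_fix_A,
    sink_fraction = 0, atom15_bias = .CAL$bias_A,
    noise_sd = nsd, sampling_days = days_ab, seed = seed)
  runB <- run_scenario(
    label = "RunB", vial = vial, initial_gas = spike(base_B),
    initial_biomass = .CAL$B0_AB, growth_rate = .CAL$mu_B,
    k_red = .CAL$k_red_B, Vmax_fix = .CAL$Vmax_fix_B,
    sink_fraction = .CAL$sink_B, atom15_bias = 0,
    noise_sd = nsd, sampling_days = days_ab, seed = seed)
  runC <- update_scenario(runB, label = "RunC_blank", initial_biomass = 0,
                          sink_fraction = 0)
  ara <- run_scenario(
    label = "ARA", vial = vial,
    initial_gas = mixture_from_volumes(c(He = 85, CO2 = 5, C2H2 = 10)),
    initial_biomass = .CAL$B0_ARA, growth_rate = .CAL$mu_ARA,
    Vmax_eth = .CAL$Vmax_eth_ARA,
    noise_sd = nsd, sampling_days = seq(0, 12, by = 2), seed = seed)

  o2_mix <- list(c(He = 95, O2 = 0, CO2 = 5), c(He = 90, O2 = 5, CO2 = 5),
                 c(He = 75, O2 = 20, CO2 = 5), c(He = 65, O2 = 30, CO2 = 5))
  o2_series <- lapply(seq_along(o2_mix), function(i) {
    v <- o2_mix[[i]]
    run_scenario(
      label = sprintf("O2_run%d", i), vial = vial,
      initial_gas = spike(mixture_from_volumes(v[v > 0])),
      initial_biomass = .CAL$B0_ARA, growth_rate = .CAL$mu_B,
      k_red = .CAL$k_red_B, Vmax_fix = .CAL$Vmax_fix_B,
      O2_inhibition_K = 0.2, sink_fraction = .CAL$sink_B,
      noise_sd = nsd, sampling_days = seq(0, 12, by = 2), seed = seed + i)
  })
  names(o2_series) <- sprintf("O2_run%d", seq_along(o2_series))

  list(RunA = runA, RunB = runB, RunC_blank = runC, ARA = ara,
       O2_series = o2_series)
}
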