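#' Freshwater N2O solubility model
#'
#' Temperature-dependent Henry solubility of nitrous oxide in fresh water
#' (salinity 0), using the Weiss & Price (1980) moist-air fit
#' `ln K0 = A1 + A2 (100/T) + A3 ln(T/100)` with K0 in mol L^-1 atm^-1.
#' Coefficients are overridable for sensitivity analyses.
#'
#' @param a1,a2,a3 Fit coefficients.
#' @param t_min,t_max Valid temperature range, K (0-40 C by default).
#'
#' @return An object of class `solubility_model`.
#' @export
solubility_model <- function(a1 = -62.7062, a2 = 97.3066, a3 = 24.1406,
                             t_min = 273.15, t_max = 313.15) {
  structure(list(a1 = a1, a2 = a2, a3 = a3, t_min = t_min, t_max = t_max),
            class = "solubility_model")
}

#' Henry solubility of N2O
#'
#' Evaluates the freshwater solubility fit at temperature `T`.
#'
#' @param temperature Temperature, K; must lie in the model's valid range.
#' @param model A [solubility_model()].
#'
#' @return Solubility K0 in mol L^-1 atm^-1 (about 0.0248 at 25 C).
#' @export
#' @examples
#' henry_constant_n2o(298.15)
henry_constant_n2o <- function(temperature, model = solubility_model()) {
  stopifnot(inherits(model, "solubility_model"))
  if (any(temperature < model$t_min | temperature > model$t_max)) {
    stop(sprintf("temperature outside the solubility fit's valid range [%g, %g] K",
                 model$t_min, model$t_max), call. = FALSE)
  }
  exp(model$a1 + model$a2 * (100 / temperature) +
        model$a3 * log(temperature / 100))
}

#' Dissolved N2O amount at gas-liquid equilibrium
#'
#' Henry's-law amount of a gas dissolved in the medium, assuming
#' instantaneous equilibration (vials shaken): `n = x P K0 V_liq`.
#'
#' @param state A [gas_state()].
#' @param vial A [vial_config()].
#' @param K0 Solubility, mol L^-1 atm^-1 (from [henry_constant_n2o()]).
#' @param species Species partitioned; default the 46N2O tracer.
#'
#' @return Dissolved amount, umol.
#' @export
dissolved_amount <- function(state, vial, K0 = henry_constant_n2o(vial$temperature),
                             species = "N2O_46") {
  stopifnot(inherits(state, "gas_state"), inherits(vial, "vial_config"))
  .assert_species(species)
  x <- unclass(state)[species]
  unname(x * vial$pressure * K0 * (vial$liquid_volume / 1000)) * 1e6
}

#' Total (headspace + dissolved) pool of a gas
#'
#' The two-phase amount used by budget accounting: "consumed N2O" covers
#' both the headspace and the dissolved pool.
#'
#' @inheritParams dissolved_amount
#' @return Total amount, umol.
#' @export
total_pool <- function(state, vial, K0 = henry_constant_n2o(vial$temperature),
                       species = "N2O_46") {
  moles_of(state, species, vial) + dissolved_amount(state, vial, K0, species)
}

# two-phase capacity of the vial for a partitioned gas, umol per atm of
# partial pressure: alpha (headspace, ideal gas) + beta (Henry)
.phase_capacity <- function(vial, K0) {
  alpha <- (vial$headspace_volume / 1000) / (.R_GAS * vial$temperature)
  beta <- K0 * (vial$liquid_volume / 1000)
  c(alpha = alpha * 1e6, beta = beta * 1e6)
}
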