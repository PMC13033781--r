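#' Sealed incubation vial geometry
#'
#' Describes one sealed batch vial: total volume, liquid (medium) volume,
#' the headspace left over, temperature and total pressure. A separate
#' `nominal_volume` (the introduced-gas volume, typically equal to the
#' total vial volume) is the basis on which ppm mixing ratios of spikes are
#' quoted, while molar amounts always use the actual headspace volume.
#'
#' @param total_volume Total vial volume, mL.
#' @param liquid_volume Medium volume, mL.
#' @param temperature Incubation temperature, K.
#' @param pressure Total pressure, atm (sampling-induced changes ignored).
#' @param nominal_volume Gas volume basis for ppm bookkeeping, mL; defaults
#'   to `total_volume`.
#'
#' @return An object of class `vial_config` with fields `total_volume`,
#'   `liquid_volume`, `headspace_volume`, `temperature`, `pressure`,
#'   `nominal_volume`.
#' @export
#' @examples
#' vial_config() # the 100 mL vial with 30 mL medium at 25 C
vial_config <- function(total_volume = 100, liquid_volume = 30,
                        temperature = 298.15, pressure = 1,
                        nominal_volume = total_volume) {
  headspace <- total_volume - liquid_volume
  if (!is.finite(headspace) || headspace <= 0) {
    stop("headspace volume (total - liquid) must be positive", call. = FALSE)
  }
  if (liquid_volume < 0) stop("liquid_volume must be >= 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (pressure <= 0) stop("pressure must be positive", call. = FALSE)
  structure(
    list(total_volume = total_volume, liquid_volume = liquid_volume,
         headspace_volume = headspace, temperature = temperature,
         pressure = pressure, nominal_volume = nominal_volume),
    class = "vial_config")
}

#' @export
print.vial_config <- function(x, ...) {
  cat(sprintf(
    "<vial_config> %g mL total, %g mL liquid, %g mL headspace, %.2f K, %g atm\n",
    x$total_volume, x$liquid_volume, x$headspace_volume,
    x$temperature, x$pressure))
  invisible(x)
}

#' Headspace gas composition
#'
#' A named vector of mole fractions over the controlled species vocabulary
#' (see [gas_species()]). Fractions must lie in \[0, 1\] and sum to 1 within
#' 1e-9; species not mentioned are zero.
#'
#' @param ... Named mole fractions, e.g. `He = 0.95, CO2 = 0.05`, or a
#'   single named numeric vector.
#'
#' @return An object of class `gas_state`: a full-length named numeric
#'   vector of mole fractions.
#' @export
#' @examples
#' gas_state(He = 0.95, CO2 = 0.05)
gas_state <- function(...) {
  args <- list(...)
  x <- if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    args[[1]]
  } else {
    unlist(args)
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("gas_state components must be named", call. = FALSE)
  }
  .assert_species(names(x))
  full <- stats::setNames(numeric(length(gas_species())), gas_species())
  full[names(x)] <- x
  .validate_gas_state(full)
}

.validate_gas_state <- function(full) {
  if (any(full < 0) || any(full > 1)) {
    stop("mole fractions must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(full)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("mole fractions must sum to 1 (got %.12f)", s), call. = FALSE)
  }
  structure(full, class = "gas_state")
}

#' @export
print.gas_state <- function(x, ...) {
  nz <- x[x > 0]
  cat("<gas_state>", paste(sprintf("%s=%g", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Gas mixture from component volumes
#'
#' Converts the volumes of gases introduced into a vial (e.g. "95 mL He,
#' 5 mL CO2") into mole fractions, assuming ideal mixing at common
#' temperature and pressure.
#'
#' @param volumes Named numeric vector of component volumes (mL), names from
#'   [gas_species()].
#'
#' @return A [gas_state()].
#' @export
#' @examples
#' mixture_from_volumes(c(N2_28 = 75, O2 = 20, CO2 = 5))
mixture_from_volumes <- function(volumes) {
  .assert_species(names(volumes))
  if (any(volumes < 0)) stop("component volumes must be >= 0", call. = FALSE)
  tot <- sum(volumes)
  if (tot <= 0) stop("at least one component volume must be positive",
                     call. = FALSE)
  gas_state(volumes / tot)
}

#' Add a gas spike to a base mixture
#'
#' Dilution bookkeeping for adding a small volume of spike gas (of given
#' purity in the spiked species) to a base gas volume: the spike species
#' gains `spike_volume * spike_purity`, every species is rescaled by the
#' enlarged total volume.
#'
#' @param base A [gas_state()].
#' @param base_volume Volume of the base gas, mL.
#' @param spike_volume Volume of spike gas added, mL.
#' @param spike_purity Fraction of the spike gas that is `spike_species`.
#'   The remainder of the spike is ignored as inert carrier already present
#'   in the base (it is assigned to the base's dominant species).
#' @param spike_species Species name from [gas_species()].
#'
#' @return A [gas_state()] for the spiked mixture.
#' @export
#' @examples
#' base <- gas_state(He = 0.95, CO2 = 0.05)
#' spiked <- apply_spike(base, 100, 0.1, 0.10, "N2O_46")
#' spiked["N2O_46"] * 1e6 # ~100 ppm
apply_spike <- function(base, base_volume, spike_volume, spike_purity,
                        spike_species) {
  stopifnot(inherits(base, "gas_state"))
  .assert_species(spike_species)
  if (spike_volume < 0 || base_volume <= 0) {
    stop("volumes must be nonnegative (base volume positive)", call. = FALSE)
  }
  if (spike_purity < 0 || spike_purity > 1) {
    stop("spike_purity must lie in [0, 1]", call. = FALSE)
  }
  if (spike_volume == 0) return(base)
  v <- unclass(base) * base_volume
  v[spike_species] <- v[spike_species] + spike_volume * spike_purity
  # spike carrier: attribute to the base's most abundant species
  carrier <- names(which.max(unclass(base)))
  v[carrier] <- v[carrier] + spike_volume * (1 - spike_purity)
  gas_state(v / (base_volume + spike_volume))
}

#' Molar amount of one species in the headspace
#'
#' Ideal-gas conversion `n = x P V / (R T)` using the actual headspace
#' volume of the vial.
#'
#' @param state A [gas_state()].
#' @param species Species name.
#' @param vial A [vial_config()].
#'
#' @return Amount in umol.
#' @export
#' @examples
#' v <- vial_config()
#' moles_of(gas_state(He = 1 - 1e-4, N2O_46 = 1e-4), "N2O_46", v)
moles_of <- function(state, species, vial) {
  stopifnot(inherits(state, "gas_state"), inherits(vial, "vial_config"))
  .assert_species(species)
  x <- unclass(state)[species]
  n_mol <- x * vial$pressure * (vial$headspace_volume / 1000) /
    (.R_GAS * vial$temperature)
  unname(n_mol) * 1e6
}

#' Nitrogen mass of a molar amount
#'
#' Converts umol of a nitrogen-bearing species to ug-N using the nominal
#' mass convention (14 ug-N per umol of N atoms, for all isotopologues).
#'
#' @param amount Amount in umol.
#' @param species Species name; must contain nitrogen.
#'
#' @return Mass in ug-N.
#' @export
#' @examples
#' nitrogen_mass(1, "N2_30") # 28 ug-N
nitrogen_mass <- function(amount, species) {
  .assert_species(species)
  k <- .n_atoms[[species]]
  if (k == 0) {
    stop("species '", species, "' contains no nitrogen", call. = FALSE)
  }
  if (any(amount < 0)) stop("amount must be >= 0", call. = FALSE)
  amount * k * 14
}
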