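#' Controlled gas-species vocabulary
#'
#' Fixed species identifiers used across all gas states, time-series CSV
#' files and scenario configurations. Isotopologues are named by their
#' nominal molecular mass: `"N2O_46"` is the doubly 15N-labelled tracer
#' (15N15N16O), `"N2_30"` is 15N15N produced from its reduction, and
#' `"N2_28"` is ambient dinitrogen (carried at natural 15N abundance;
#' 29N2 is not tracked).
#'
#' @return Character vector of valid species names.
#' @export
#' @examples
#' gas_species()
gas_species <- function() {
  c("He", "N2_28", "N2_30", "O2", "CO2", "N2O_44", "N2O_46", "C2H2", "C2H4")
}

# nitrogen atoms per molecule (nominal-mass convention: 14 ug-N per umol N)
.n_atoms <- c(
  He = 0, N2_28 = 2, N2_30 = 2, O2 = 0, CO2 = 0,
  N2O_44 = 2, N2O_46 = 2, C2H2 = 0, C2H4 = 0
)

#' Natural 15N abundance
#'
#' Atom fraction of 15N in atmospheric nitrogen, the baseline against which
#' tracer enrichment ("atom percent excess") is measured.
#'
#' @return A single numeric, 0.00366 (0.366 atom percent).
#' @export
natural_abundance_15N <- function() 0.00366

# ideal-gas constant, L atm K^-1 mol^-1
.R_GAS <- 0.082057366

.assert_species <- function(species) {
  bad <- setdiff(species, gas_species())
  if (length(bad) > 0L) {
    stop("unknown species: ", paste(bad, collapse = ", "),
         " (valid: ", paste(gas_species(), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(species)
}
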