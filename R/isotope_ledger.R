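#' Nitrogen pool with 15N atom fraction
#'
#' A mass of nitrogen (ug-N, nominal 14 g/mol convention) together with its
#' 15N atom fraction. Biomass IR-MS readings enter the pipeline as such
#' pairs; gas pools are converted to them for budget arithmetic.
#'
#' @param total_N Total nitrogen mass, ug-N (>= 0).
#' @param atom15 15N atom fraction in \[0, 1\].
#'
#' @return An object of class `isotope_pool`.
#' @export
#' @examples
#' isotope_pool(1000, 0.01366)
isotope_pool <- function(total_N, atom15) {
  if (total_N < 0) stop("total_N must be >= 0", call. = FALSE)
  if (atom15 < 0 || atom15 > 1) stop("atom15 must lie in [0, 1]", call. = FALSE)
  structure(list(total_N = total_N, atom15 = atom15), class = "isotope_pool")
}

#' @export
print.isotope_pool <- function(x, ...) {
  cat(sprintf("<isotope_pool> %.6g ug-N at %.5f atom fraction 15N\n",
              x$total_N, x$atom15))
  invisible(x)
}

#' 15N atom-fraction excess over a baseline
#'
#' The pool's atom fraction minus the baseline (natural abundance by
#' default). Negative values can arise from measurement bias and are
#' retained, bounded below by `-baseline`.
#'
#' @param pool An [isotope_pool()].
#' @param baseline Baseline atom fraction in \[0, 1).
#'
#' @return Atom-fraction excess (dimensionless).
#' @export
#' @examples
#' atom_excess(isotope_pool(100, 0.01366)) # 0.01
atom_excess <- function(pool, baseline = natural_abundance_15N()) {
  stopifnot(inherits(pool, "isotope_pool"))
  if (baseline < 0 || baseline >= 1) {
    stop("baseline must lie in [0, 1)", call. = FALSE)
  }
  max(pool$atom15 - baseline, -baseline)
}

#' Excess 15N mass of a pool
#'
#' `total_N * atom_excess`: the mass of 15N above the natural-abundance
#' background — the "fixed, N2O-derived nitrogen" term of the budget.
#'
#' @inheritParams atom_excess
#' @return Mass in ug-N (can be negative under measurement bias).
#' @export
#' @examples
#' excess_15N_mass(isotope_pool(1000, 0.01366)) # 10 ug-N
excess_15N_mass <- function(pool, baseline = natural_abundance_15N()) {
  pool$total_N * atom_excess(pool, baseline)
}

#' Mix two isotope pools
#'
#' Mass-weighted mixing: total nitrogen adds, the atom fraction is the
#' mass-weighted mean, so 15N mass is conserved exactly.
#'
#' @param a,b [isotope_pool()] objects.
#'
#' @return The mixed [isotope_pool()]. Mixing two empty pools returns an
#'   empty pool at natural abundance.
#' @export
#' @examples
#' mix_pools(isotope_pool(3, 0.1), isotope_pool(1, 0.5)) # 4 ug-N at 0.2
mix_pools <- function(a, b) {
  stopifnot(inherits(a, "isotope_pool"), inherits(b, "isotope_pool"))
  tot <- a$total_N + b$total_N
  if (tot == 0) return(isotope_pool(0, natural_abundance_15N()))
  isotope_pool(tot, (a$total_N * a$atom15 + b$total_N * b$atom15) / tot)
}

#' Fraction of nitrogenase flux drawn from 30N2
#'
#' When both ambient 28N2 and tracer-derived 30N2 are present, fixation
#' draws on them in proportion to their partial pressures; this fraction
#' labels the biomass nitrogen gained by fixation.
#'
#' @param p28 Amount or partial pressure of 28N2 (>= 0).
#' @param p30 Amount or partial pressure of 30N2 (>= 0), same units as `p28`.
#'
#' @return `p30 / (p28 + p30)`.
#' @export
#' @examples
#' isotopologue_split(0.95, 1e-4)
isotopologue_split <- function(p28, p30) {
  if (p28 < 0 || p30 < 0) stop("amounts must be >= 0", call. = FALSE)
  tot <- p28 + p30
  if (tot == 0) {
    stop("isotopologue split undefined: total N2 is zero", call. = FALSE)
  }
  p30 / tot
}
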