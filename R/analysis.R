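#' Linear consumption/production rate from a time series
#'
#' Ordinary least-squares fit of a species' nitrogen amount (ug-N,
#' headspace + dissolved for partitioned N2O) against time, on replicate
#' means per sampling day, within a day window. The specific rate is the
#' magnitude of the slope normalised by dry biomass.
#'
#' @param ts Long time series with gas channels as partial pressures (atm).
#' @param species Species channel to fit (default `"N2O_46"`).
#' @param window Numeric length-2 day range (inclusive), default the full
#'   series.
#' @param biomass Dry biomass used for normalisation, g (> 0). If `NULL`,
#'   the replicate-mean `biomass` channel at the last day of the window is
#'   used (harvest convention).
#' @param vial A [vial_config()].
#' @param K0 N2O solubility for the dissolved pool (mol L^-1 atm^-1).
#'
#' @return An object of class `rate_estimate` with fields `slope` (ug-N/day,
#'   signed), `intercept` (ug-N), `r_squared`, `specific_rate`
#'   (ug-N g^-1 day^-1), `fit_window`, `n_points`, `biomass`.
#' @export
fit_consumption_rate <- function(ts, species = "N2O_46",
                                 window = range(ts$day), biomass = NULL,
                                 vial = vial_config(),
                                 K0 = henry_constant_n2o(vial$temperature)) {
  .assert_species(species)
  sub <- ts[ts$variable == species & ts$day >= window[1] & ts$day <= window[2], ]
  days <- sort(unique(sub$day))
  if (length(days) < 2) {
    stop("need at least two sampling days in the fit window", call. = FALSE)
  }
  if (is.null(biomass)) {
    biomass <- mean(ts$value[ts$variable == "biomass" & ts$day == max(days)])
  }
  if (!is.finite(biomass) || biomass <= 0) {
    stop("biomass for normalisation must be positive", call. = FALSE)
  }
  cap <- .phase_capacity(vial, K0)
  per_atm <- if (species == "N2O_46") cap[["alpha"]] + cap[["beta"]] else
    cap[["alpha"]]
  mean_p <- tapply(sub$value, sub$day, mean)
  amount <- unname(mean_p) * per_atm * .n_atoms[[species]] * 14  # ug-N
  fit <- stats::lm(amount ~ days)
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((amount - mean(amount))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, specific_rate = abs(slope) / biomass,
         fit_window = range(days), n_points = length(days),
         biomass = biomass, species = species),
    class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> %s: slope %.4g ug-N/day (r2 = %.4f, %d days %g-%g)\n  specific rate %.4g ug-N/g/day over %.3g g dry biomass\n",
    x$species, x$slope, x$r_squared, x$n_points,
    x$fit_window[1], x$fit_window[2], x$specific_rate, x$biomass))
  invisible(x)
}

#' Percent slowdown of one rate relative to another
#'
#' `100 (1 - rate_a / rate_b)`: how much slower condition A is than the
#' reference condition B.
#'
#' @param rate_a,rate_b Specific rates, same units; `rate_b > 0`.
#' @return Percent.
#' @export
#' @examples
#' percent_slowdown(48.7, 127) # ~62
percent_slowdown <- function(rate_a, rate_b) {
  if (rate_b <= 0) stop("reference rate must be positive", call. = FALSE)
  100 * (1 - rate_a / rate_b)
}

#' Percent retardation of cumulative consumption at a target day
#'
#' Compares the cumulative consumed amount (initial pool minus pool at
#' `day`, headspace + dissolved) of a species between two runs:
#' `100 (1 - consumed_a / consumed_b)`.
#'
#' @param ts_a,ts_b Long time series covering `day`.
#' @param species Species channel (default `"N2O_46"`).
#' @param day Evaluation day.
#' @param vial A [vial_config()].
#' @param K0 Solubility for the dissolved pool.
#' @return Percent.
#' @export
cumulative_retardation <- function(ts_a, ts_b, species = "N2O_46", day,
                                   vial = vial_config(),
                                   K0 = henry_constant_n2o(vial$temperature)) {
  consumed <- function(ts) {
    sub <- ts[ts$variable == species, ]
    if (!day %in% sub$day) {
      stop("series does not cover day ", day, call. = FALSE)
    }
    p0 <- mean(sub$value[sub$day == min(sub$day)])
    pd <- mean(sub$value[sub$day == day])
    cap <- .phase_capacity(vial, K0)
    per_atm <- if (species == "N2O_46") cap[["alpha"]] + cap[["beta"]] else
      cap[["alpha"]]
    (p0 - pd) * per_atm * .n_atoms[[species]] * 14
  }
  cb <- consumed(ts_b)
  if (cb <= 0) stop("reference run shows no net consumption", call. = FALSE)
  100 * (1 - consumed(ts_a) / cb)
}

#' Convert an acetylene-reduction rate to a nitrogen-fixation rate
#'
#' Applies the classical C2H4:N2 = 3:1 molar stoichiometry: umol N2 fixed =
#' umol C2H4 produced / ratio, reported as ug-N (x 28) per g per day.
#'
#' @param ethylene_rate Specific ethylene production rate,
#'   umol C2H4 g^-1 day^-1 (>= 0).
#' @param ratio Molar conversion ratio (mol C2H4 per mol N2), default 3.
#' @return Specific fixation rate, ug-N g^-1 day^-1.
#' @export
#' @examples
#' ara_to_fixation(3) # 28
ara_to_fixation <- function(ethylene_rate, ratio = 3) {
  if (any(ethylene_rate < 0)) stop("ethylene rate must be >= 0", call. = FALSE)
  if (ratio <= 0) stop("conversion ratio must be positive", call. = FALSE)
  ethylene_rate / ratio * 28
}

#' N2O fixation rate as a percentage of the N2 fixation rate
#'
#' @param n2o_rate,n2_rate Specific rates, same units; `n2_rate > 0`.
#' @return Percent.
#' @export
#' @examples
#' fixation_fraction(48.7, 24600) # ~0.20
fixation_fraction <- function(n2o_rate, n2_rate) {
  if (n2_rate <= 0) stop("N2 fixation rate must be positive", call. = FALSE)
  100 * n2o_rate / n2_rate
}

#' Convert a per-cell rate to a specific (per dry mass) rate
#'
#' Divides a per-cell nitrogen rate by the dry mass per cell (0.28 pg by
#' default) and normalises to ug-N per g dry biomass per day.
#'
#' @param rate_per_cell Per-cell rate, fg-N cell^-1 day^-1.
#' @param cell_dry_mass Dry mass per cell, pg (> 0); default 0.28.
#' @return Specific rate, ug-N g^-1 day^-1.
#' @export
#' @examples
#' per_cell_to_specific(1) # ~3571
per_cell_to_specific <- function(rate_per_cell, cell_dry_mass = 0.28) {
  if (cell_dry_mass <= 0) stop("cell dry mass must be positive", call. = FALSE)
  # fg/cell/day -> g-N per g dry per day -> ug-N per g per day
  (rate_per_cell * 1e-15) / (cell_dry_mass * 1e-12) * 1e6
}

#' Nitrogen budget closure for one run
#'
#' Accounts for the fate of the 46N2O tracer between the first and last
#' (or given) sampling days: `consumed` is the decrease of the two-phase
#' N2O pool (ug-N), `emitted` the final headspace 30N2 (ug-N), `fixed` the
#' tracer-derived nitrogen in biomass computed from the 15N excess scaled
#' to the tracer's atom fraction
#' (`total_N (atom15 - baseline) / (1 - baseline)`; the spike is fully
#' labelled). `closure = 100 (emitted + fixed) / consumed`;
#' `missing = 100 - closure`. With no unmeasured sink, no measurement bias
#' and no noise, closure is exactly 100 by conservation.
#'
#' @param ts Long time series with an `N2O_46` and an `N2_30` channel.
#' @param biomass_pool End-point biomass [isotope_pool()]; defaults to the
#'   replicate-mean biomass channels at the final day of `ts`.
#' @param vial A [vial_config()].
#' @param K0 N2O solubility.
#' @param baseline Natural-abundance atom fraction.
#' @param day_initial,day_final Budget window; default first and last
#'   sampled days.
#'
#' @return An object of class `budget_report` with fields `consumed_N2O`,
#'   `emitted_30N2`, `fixed_15N_excess` (all ug-N), `closure`, `missing`
#'   (percent), and `flag` (`"ok"` or `"no net consumption"`, in which case
#'   closure is `NA`).
#' @export
close_budget <- function(ts, biomass_pool = biomass_pool_at(ts),
                         vial = vial_config(),
                         K0 = henry_constant_n2o(vial$temperature),
                         baseline = natural_abundance_15N(),
                         day_initial = min(ts$day), day_final = max(ts$day)) {
  stopifnot(inherits(biomass_pool, "isotope_pool"))
  cap <- .phase_capacity(vial, K0)
  pool_at <- function(d, sp, per_atm) {
    v <- ts$value[ts$variable == sp & ts$day == d]
    if (length(v) == 0) stop("no ", sp, " observation at day ", d, call. = FALSE)
    mean(v) * per_atm * 28
  }
  two_phase <- cap[["alpha"]] + cap[["beta"]]
  consumed <- pool_at(day_initial, "N2O_46", two_phase) -
    pool_at(day_final, "N2O_46", two_phase)
  emitted <- pool_at(day_final, "N2_30", cap[["alpha"]]) -
    pool_at(day_initial, "N2_30", cap[["alpha"]])
  fixed <- excess_15N_mass(biomass_pool, baseline) / (1 - baseline)
  if (consumed <= 0) {
    rep <- list(consumed_N2O = consumed, emitted_30N2 = emitted,
                fixed_15N_excess = fixed, closure = NA_real_,
                missing = NA_real_, flag = "no net consumption")
  } else {
    closure <- 100 * (emitted + fixed) / consumed
    rep <- list(consumed_N2O = consumed, emitted_30N2 = emitted,
                fixed_15N_excess = fixed, closure = closure,
                missing = 100 - closure, flag = "ok")
  }
  structure(rep, class = "budget_report")
}

#' @export
print.budget_report <- function(x, ...) {
  if (x$flag != "ok") {
    cat("<budget_report> flagged:", x$flag, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<budget_report> consumed %.3f ug-N; emitted 30N2 %.3f; fixed (15N excess) %.3f\n  closure %.1f%%, missing %.1f%%\n",
    x$consumed_N2O, x$emitted_30N2, x$fixed_15N_excess, x$closure, x$missing))
  invisible(x)
}

#' Specific ethylene production rate from an ARA time series
#'
#' OLS fit of the headspace ethylene amount (umol) against time on
#' replicate means, normalised by dry biomass — the quantity the 3:1
#' conversion ([ara_to_fixation()]) turns into an N2-fixation rate.
#'
#' @param ts Long time series with a `C2H4` channel (partial pressure, atm).
#' @param window Day range of the fit (default full series).
#' @param biomass Dry biomass, g; defaults to the replicate-mean `biomass`
#'   channel at the last day of the window (harvest convention).
#' @param vial A [vial_config()].
#'
#' @return A list with `specific_rate_umol` (umol C2H4 g^-1 day^-1) and
#'   `fit` (a `rate_estimate`-like record of the underlying OLS fit in
#'   umol/day).
#' @export
ethylene_rate <- function(ts, window = range(ts$day), biomass = NULL,
                          vial = vial_config()) {
  sub <- ts[ts$variable == "C2H4" & ts$day >= window[1] & ts$day <= window[2], ]
  days <- sort(unique(sub$day))
  if (length(days) < 2) {
    stop("need at least two sampling days in the fit window", call. = FALSE)
  }
  if (is.null(biomass)) {
    biomass <- mean(ts$value[ts$variable == "biomass" & ts$day == max(days)])
  }
  if (!is.finite(biomass) || biomass <= 0) {
    stop("biomass for normalisation must be positive", call. = FALSE)
  }
  alpha <- .phase_capacity(vial, 0)[["alpha"]]
  amount <- unname(tapply(sub$value, sub$day, mean)) * alpha  # umol
  fit <- stats::lm(amount ~ days)
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((amount - mean(amount))^2)
  est <- structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = if (sst == 0) 1 else
           1 - sum(stats::residuals(fit)^2) / sst,
         specific_rate = abs(slope) / biomass,
         fit_window = range(days), n_points = length(days),
         biomass = biomass, species = "C2H4"),
    class = "rate_estimate")
  list(specific_rate_umol = abs(slope) / biomass, fit = est)
}
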