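#' Forward simulation of a closed-vial incubation
#'
#' Integrates the closed-vial model with fixed-step RK4 (step
#' `scenario$step` day): two-step transfer of the 46N2O tracer (reduction
#' to 30N2, then fixation of headspace N2 into biomass with an
#' isotopologue-proportional 15N label), exponential growth gated by the
#' light duty cycle, photosynthetic O2 release proportional to growth, an
#' unmeasured sink intercepting a fixed fraction of reduced N2O, optional
#' O2 inhibition of uptake, acetylene reduction to ethylene (which
#' suppresses N2 fixation), and instantaneous Henry's-law partitioning of
#' N2O between headspace and medium at every step.
#'
#' The return value is the noise-free state trajectory at the scenario's
#' sampling days, in long format. Gas channels are partial pressures
#' (`unit = "atm"`, computed as n R T / V_headspace; for N2O_46 the
#' headspace share of the two-phase pool); biomass channels are dry mass
#' (`biomass`, g), nitrogen content (`biomass_N`, ug-N) and 15N atom
#' fraction (`atom15`). Diagnostic channels `sink_N` (ug-N routed to the
#' unmeasured pool) and `dissolved_N2O_46` (umol) are included with
#' replicate 0.
#'
#' @param scenario A [run_scenario()].
#'
#' @return A `data.frame` with columns
#'   `vial_id, run, replicate, day, variable, value, unit` (one simulated
#'   truth, `replicate = 0`).
#' @export
#' @examples
#' sc <- packaged_scenarios(noise = FALSE)$RunB
#' ts <- simulate_incubation(sc)
#' head(ts)
simulate_incubation <- function(scenario) {
  stopifnot(inherits(scenario, "run_scenario"))
  sc <- scenario
  vial <- sc$vial
  K0 <- henry_constant_n2o(vial$temperature)
  cap <- .phase_capacity(vial, K0)        # umol/atm: alpha headspace, beta liquid
  alpha <- cap[["alpha"]]; beta <- cap[["beta"]]
  nat <- natural_abundance_15N()

  x0 <- unclass(sc$initial_gas)
  # initial amounts, umol; N2O_46 as a two-phase total (spiked gas
  # equilibrates with the medium on a timescale << 1 day)
  p0 <- x0 * vial$pressure
  y0 <- c(
    n46 = unname(p0[["N2O_46"]] * (alpha + beta)),
    n30 = unname(p0[["N2_30"]] * alpha),
    n28 = unname(p0[["N2_28"]] * alpha),
    nO2 = unname(p0[["O2"]] * alpha),
    nC2H2 = unname(p0[["C2H2"]] * alpha),
    nC2H4 = unname(p0[["C2H4"]] * alpha),
    nsink = 0,
    B = sc$initial_biomass,
    bioN = sc$initial_biomass * sc$biomass_N_frac * 1e6,  # ug-N
    bio15N = sc$initial_biomass * sc$biomass_N_frac * 1e6 * nat
  )

  deriv <- function(t, y, parms) {
    p46 <- y[["n46"]] / (alpha + beta)       # atm, two-phase equilibrium
    p30 <- y[["n30"]] / alpha
    p28 <- y[["n28"]] / alpha
    pO2 <- y[["nO2"]] / alpha
    pC2H2 <- y[["nC2H2"]] / alpha
    B <- y[["B"]]

    v_red <- switch(sc$rate_law_mode,
      empirical_first_order = sc$k_red * p46,
      competitive_MM = {
        if (is.na(sc$K_N2O)) stop("competitive_MM mode requires K_N2O",
                                  call. = FALSE)
        sc$Vmax_red * p46 / (sc$K_N2O * (1 + p28 / sc$Km_N2) + p46)
      })
    if (!is.na(sc$O2_inhibition_K)) {
      v_red <- v_red / (1 + pO2 / sc$O2_inhibition_K)
    }

    acetylene <- pC2H2 > 1e-12
    pN2 <- p28 + p30
    if (acetylene || pN2 <= 0) {
      v_fix <- 0
      f30 <- 0
    } else {
      denom <- if (is.na(sc$K_N2O)) sc$Km_N2 else
        sc$Km_N2 * (1 + p46 / sc$K_N2O)
      v_fix <- sc$Vmax_fix * pN2 / (denom + pN2)
      f30 <- p30 / pN2
    }
    v_eth <- if (acetylene) {
      sc$Vmax_eth * pC2H2 / (sc$Ks_C2H2 + pC2H2)
    } else 0

    red <- v_red * B                      # umol N2O/day consumed
    fix <- v_fix * B                      # umol N2/day fixed
    eth <- v_eth * B                      # umol C2H4/day produced
    s <- sc$sink_fraction
    dB <- sc$growth_rate * sc$light_duty_cycle * B

    list(c(
      n46 = -red,
      n30 = (1 - s) * red - fix * f30,
      n28 = -fix * (1 - f30),
      nO2 = sc$O2_yield * dB,
      nC2H2 = -eth,
      nC2H4 = eth,
      nsink = s * red,
      B = dB,
      bioN = 28 * fix,
      bio15N = 28 * fix * (f30 + (1 - f30) * nat)
    ))
  }

  days <- sc$sampling_days
  t_end <- max(days)
  times <- sort(unique(c(seq(0, t_end, by = sc$step), days, t_end)))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  if (anyNA(sol) || nrow(sol) < length(times)) {
    stop("integration failed: non-finite state encountered; ",
         "check rate constants and step size", call. = FALSE)
  }
  sol <- as.data.frame(sol)
  idx <- vapply(days, function(d) which.min(abs(sol$time - d)), integer(1))
  out <- sol[idx, , drop = FALSE]

  rows <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    r <- out[i, ]
    p46_tot <- r$n46 / (alpha + beta)
    data.frame(
      day = days[i],
      variable = c("N2O_46", "N2_30", "N2_28", "O2", "C2H2", "C2H4",
                   "biomass", "biomass_N", "atom15",
                   "sink_N", "dissolved_N2O_46"),
      value = c(p46_tot,                   # headspace partial pressure, atm
                r$n30 / alpha, r$n28 / alpha, r$nO2 / alpha,
                r$nC2H2 / alpha, r$nC2H4 / alpha,
                r$B, r$bioN,
                if (r$bioN > 0) r$bio15N / r$bioN else natural_abundance_15N(),
                28 * r$nsink,
                p46_tot * beta),
      unit = c(rep("atm", 6), "g", "ug-N", "fraction", "ug-N", "umol"),
      stringsAsFactors = FALSE)
  }))
  ts <- data.frame(vial_id = paste0(sc$label, "_sim"), run = sc$label,
                   replicate = 0L, rows, stringsAsFactors = FALSE)
  class(ts) <- c("vial_timeseries", "data.frame")
  ts
}

#' Total 15N and 14N of a simulated trajectory
#'
#' Closed-vial isotope ledger at each sampled day: 15N summed over the
#' two-phase 46N2O pool, 30N2, the natural-abundance share of ambient
#' 28N2, biomass and the unmeasured sink; 14N as the complement. Used by
#' the conservation checks.
#'
#' @param ts A noise-free trajectory from [simulate_incubation()].
#' @param vial The [vial_config()] the trajectory was simulated in.
#'
#' @return A `data.frame` with columns `day`, `total_15N`, `total_14N`
#'   (ug-N).
#' @export
isotope_totals <- function(ts, vial = vial_config()) {
  stopifnot(inherits(ts, "data.frame"))
  nat <- natural_abundance_15N()
  wide <- .ts_wide(ts[ts$replicate == 0L, ])
  # gas partial pressures -> umol via alpha; N2O_46 via alpha+beta
  K0 <- henry_constant_n2o(vial$temperature)
  cap <- .phase_capacity(vial, K0)
  n46 <- wide$N2O_46 * (cap[["alpha"]] + cap[["beta"]])
  n30 <- wide$N2_30 * cap[["alpha"]]
  n28 <- wide$N2_28 * cap[["alpha"]]
  bio15 <- wide$biomass_N * wide$atom15
  sink15 <- wide$sink_N
  t15 <- 28 * (n46 + n30 + n28 * nat) + bio15 + sink15
  t14 <- 28 * (n28 * (1 - nat)) + (wide$biomass_N - bio15)
  data.frame(day = wide$day, total_15N = t15, total_14N = t14)
}

# long -> wide (values averaged over replicates), one row per day
.ts_wide <- function(ts) {
  agg <- stats::aggregate(value ~ day + variable, data = ts, FUN = mean)
  w <- stats::reshape(agg, idvar = "day", timevar = "variable",
                      direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  rownames(w) <- NULL
  w[order(w$day), , drop = FALSE]
}
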