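#' Apply the measurement model to a simulated trajectory
#'
#' Expands the noise-free truth into `scenario$replicates` replicate vials,
#' adds independent Gaussian noise per instrument channel
#' (`scenario$noise_sd`, channel units) and the additive systematic bias on
#' the biomass 15N atom-fraction channel (`scenario$atom15_bias`).
#' Deterministic given `scenario$seed`. Diagnostic channels (`sink_N`,
#' `dissolved_N2O_46`) are dropped: they are not observable.
#'
#' @param ts Trajectory from [simulate_incubation()].
#' @param scenario The [run_scenario()] that produced it.
#' @param clip Clip noisy gas/biomass amounts at zero (default `TRUE`;
#'   atom-fraction readings are never clipped, so negative excess survives).
#'
#' @return A long `data.frame` like `ts` with `replicate` in
#'   `1:scenario$replicates`.
#' @export
#' @examples
#' sc <- packaged_scenarios(seed = 7)$RunB
#' meas <- measure_timeseries(simulate_incubation(sc), sc)
#' table(meas$replicate)
measure_timeseries <- function(ts, scenario, clip = TRUE) {
  stopifnot(inherits(scenario, "run_scenario"))
  truth <- ts[ts$replicate == 0L &
                !(ts$variable %in% c("sink_N", "dissolved_N2O_46")), ,
              drop = FALSE]
  nsd <- scenario$noise_sd
  withr::with_seed(scenario$seed, {
    reps <- lapply(seq_len(scenario$replicates), function(r) {
      out <- truth
      out$replicate <- as.integer(r)
      out$vial_id <- sprintf("%s_r%d", scenario$label, r)
      sd_chan <- ifelse(out$variable %in% names(nsd),
                        nsd[out$variable], 0)
      out$value <- out$value + stats::rnorm(nrow(out), 0, sd_chan)
      bias_rows <- out$variable == "atom15"
      out$value[bias_rows] <- out$value[bias_rows] + scenario$atom15_bias
      if (clip) {
        amt <- out$variable != "atom15"
        out$value[amt] <- pmax(out$value[amt], 0)
      }
      out$value[out$variable == "atom15"] <-
        pmin(out$value[out$variable == "atom15"], 1)
      out
    })
    res <- do.call(rbind, reps)
  })
  rownames(res) <- NULL
  class(res) <- c("vial_timeseries", "data.frame")
  res
}

#' Biomass isotope pool at a sampled day
#'
#' Replicate-mean biomass nitrogen and atom fraction from a time series,
#' as an [isotope_pool()] for budget accounting.
#'
#' @param ts A long time series with `biomass_N` and `atom15` channels.
#' @param day Sampling day; defaults to the last day present.
#'
#' @return An [isotope_pool()].
#' @export
biomass_pool_at <- function(ts, day = max(ts$day)) {
  sub <- ts[ts$day == day & ts$variable %in% c("biomass_N", "atom15"), ]
  if (nrow(sub) == 0) stop("no biomass channels at day ", day, call. = FALSE)
  m <- tapply(sub$value, sub$variable, mean)
  isotope_pool(unname(m[["biomass_N"]]), unname(m[["atom15"]]))
}
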