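.TS_COLUMNS <- c("vial_id", "run", "replicate", "day", "variable", "value",
                 "unit")

.TS_VARIABLES <- function() {
  c(gas_species(), "biomass", "biomass_N", "atom15", "sink_N",
    "dissolved_N2O_46")
}

#' Read a long-format vial time series
#'
#' Reads and validates a measurement CSV with columns
#' `vial_id,run,replicate,day,variable,value,unit`. Variables must come
#' from the controlled vocabulary ([gas_species()] plus the biomass
#' channels `biomass`, `biomass_N`, `atom15`); offending rows are reported
#' with their line numbers.
#'
#' @param path Path to a CSV file (UTF-8, '.' decimal).
#' @return A `vial_timeseries` data.frame.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ts <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(ts) == 0) stop("empty time-series file: ", path, call. = FALSE)
  missing_cols <- setdiff(.TS_COLUMNS, names(ts))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!ts$variable %in% .TS_VARIABLES())
  if (length(bad) > 0) {
    # +1 for the header line
    stop("unknown variable(s) ",
         paste(unique(ts$variable[bad]), collapse = ", "),
         " at line(s) ", paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  nonnum <- which(!is.finite(suppressWarnings(as.numeric(ts$value))) |
                    !is.finite(suppressWarnings(as.numeric(ts$day))))
  if (length(nonnum) > 0) {
    stop("malformed numeric value(s) at line(s) ",
         paste(nonnum + 1L, collapse = ", "), call. = FALSE)
  }
  ts$value <- as.numeric(ts$value)
  ts$day <- as.numeric(ts$day)
  ts$replicate <- as.integer(ts$replicate)
  ts <- ts[, .TS_COLUMNS]
  class(ts) <- c("vial_timeseries", "data.frame")
  ts
}

#' Write a vial time series to CSV
#'
#' @param ts A long time series (as from [simulate_incubation()] or
#'   [measure_timeseries()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(all(.TS_COLUMNS %in% names(ts)))
  utils::write.csv(ts[, .TS_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.SCENARIO_SCALARS <- c(
  "label", "initial_biomass", "biomass_N_frac", "growth_rate",
  "light_duty_cycle", "rate_law_mode", "k_red", "Vmax_red", "K_N2O",
  "Km_N2", "Ks_C2H2", "Vmax_fix", "Vmax_eth", "O2_yield",
  "O2_inhibition_K", "sink_fraction", "atom15_bias", "replicates", "seed",
  "step")

#' Write a run scenario to a YAML configuration file
#'
#' The schema is versioned (`schema_version: 1`); [read_scenario()] rejects
#' unknown keys so silent parameter typos cannot corrupt calibrated
#' scenarios.
#'
#' @param scenario A [run_scenario()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "run_scenario"))
  gas <- unclass(scenario$initial_gas)
  cfg <- c(
    list(schema_version = 1L),
    unclass(scenario)[.SCENARIO_SCALARS],
    list(
      vial = scenario$vial[c("total_volume", "liquid_volume", "temperature",
                             "pressure", "nominal_volume")],
      initial_gas = as.list(gas[gas > 0]),
      noise_sd = as.list(scenario$noise_sd),
      sampling_days = scenario$sampling_days))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a run scenario from a YAML configuration file
#'
#' @param path Path written by [write_scenario()] (schema_version 1).
#' @return A [run_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version) || cfg$schema_version != 1L) {
    stop("unsupported or missing schema_version (expected 1)", call. = FALSE)
  }
  known <- c("schema_version", .SCENARIO_SCALARS, "vial", "initial_gas",
             "noise_sd", "sampling_days")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  scalars <- cfg[intersect(.SCENARIO_SCALARS, names(cfg))]
  scalars <- lapply(scalars, function(x) if (is.null(x)) NA_real_ else x)
  args <- c(
    scalars,
    list(vial = do.call(vial_config, cfg$vial),
         initial_gas = gas_state(unlist(cfg$initial_gas)),
         noise_sd = unlist(cfg$noise_sd),
         sampling_days = unlist(cfg$sampling_days)))
  if (is.null(args$noise_sd)) args$noise_sd <- numeric(0)
  do.call(run_scenario, args)
}

#' Assemble a structured run report
#'
#' Aggregates the outputs of one analysed run into a machine-readable
#' report: rate estimates, budget terms and statistics, every numeric field
#' paired with an explicit ASCII unit string, plus provenance (scenario
#' label, seed, package version, input paths).
#'
#' @param scenario The [run_scenario()] analysed (or `NULL`).
#' @param rates Named list of `rate_estimate` objects.
#' @param budget A `budget_report`, or `NULL`.
#' @param statistics Output of [anova_tukey()], or `NULL`.
#' @param inputs Character vector of input file paths (or "generated").
#'
#' @return A list of class `run_report`.
#' @export
run_report <- function(scenario = NULL, rates = list(), budget = NULL,
                       statistics = NULL, inputs = "generated") {
  fmt_rate <- function(r) list(
    slope = list(value = r$slope, unit = "ug-N/day"),
    intercept = list(value = r$intercept, unit = "ug-N"),
    r_squared = list(value = r$r_squared, unit = "dimensionless"),
    specific_rate = list(value = r$specific_rate, unit = "ug-N/g/day"),
    fit_window = list(value = r$fit_window, unit = "day"),
    n_points = list(value = r$n_points, unit = "count"),
    biomass = list(value = r$biomass, unit = "g"))
  fmt_budget <- function(b) list(
    consumed_N2O = list(value = b$consumed_N2O, unit = "ug-N"),
    emitted_30N2 = list(value = b$emitted_30N2, unit = "ug-N"),
    fixed_15N_excess = list(value = b$fixed_15N_excess, unit = "ug-N"),
    closure = list(value = b$closure, unit = "percent"),
    missing = list(value = b$missing, unit = "percent"),
    flag = b$flag)
  rep <- list(
    scenario = if (is.null(scenario)) NULL else scenario$label,
    seed = if (is.null(scenario)) NULL else scenario$seed,
    package_version = as.character(utils::packageVersion("n2otrace")),
    inputs = inputs,
    rates = lapply(rates, fmt_rate),
    budget = if (is.null(budget)) NULL else fmt_budget(budget),
    statistics = statistics)
  class(rep) <- "run_report"
  rep
}

#' Write a run report as JSON
#'
#' @param report A [run_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a run report from JSON
#'
#' @param path Path written by [write_run_report()].
#' @return A `run_report` list.
#' @export
read_run_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  class(rep) <- "run_report"
  rep
}
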