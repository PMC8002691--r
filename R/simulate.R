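# Simulate incubation experiments from a station scenario.

#' Simulate one incubation time series
#'
#' Constructs the true bottle trajectory at a depth of the scenario —
#' total N\eqn{_2}O pool \eqn{N(t) = N_0 + R\,V\,t/24} and labelled pool
#' \eqn{^{15}N(t) = {}^{15}N_0 + R\,f^{15}\,V\,t/24}, where \eqn{R} is the
#' treatment's labelled production rate (fungal + bacterial for `NO3`,
#' fungal + leakage \eqn{\times} bacterial for `NO3_CAP`, nitrification
#' for `NH4`) — then applies the observation model: multiplicative
#' mean-one lognormal noise on the N\eqn{_2}O quantity and additive
#' Gaussian noise on \eqn{\delta^{15}}N. With all noise set to zero,
#' [fit_rate()] on the output returns the true rate to floating-point
#' accuracy.
#'
#' @param scenario A [station_scenario()].
#' @param depth_m A depth on the scenario grid.
#' @param treatment `"NO3"`, `"NO3_CAP"` or `"NH4"`.
#' @param config A `run_config` (tracer additions, volume, constants).
#' @param noise A [noise_model()].
#' @param seed Optional integer; when given, draws are made under a local
#'   RNG scope (the caller's RNG state is untouched). When `NULL`, the
#'   current RNG stream is used.
#' @param timepoints_h Sampling times; defaults to the scenario's design.
#' @return An [incubation_series()].
#' @export
simulate_incubation <- function(scenario, depth_m, treatment,
                                config = default_config(),
                                noise = noise_model(),
                                seed = NULL,
                                timepoints_h = scenario$timepoints_h) {
  if (!inherits(scenario, "station_scenario")) {
    stop_validation("`scenario` must be a station_scenario")
  }
  if (!depth_m %in% scenario$depths_m) {
    stop_validation("depth %.4g m is not on the scenario grid", depth_m)
  }
  if (!treatment %in% TREATMENTS) {
    stop_validation("treatment '%s' invalid; allowed: %s", treatment,
                    paste(TREATMENTS, collapse = ", "))
  }
  if (!inherits(noise, "noise_model")) {
    stop_validation("`noise` must be a noise_model")
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop_validation("`seed` must be a single integer")
    }
    return(withr::with_seed(as.integer(seed), simulate_incubation(
      scenario, depth_m, treatment, config, noise, seed = NULL,
      timepoints_h = timepoints_h)))
  }

  constants <- config_constants(config)
  ambient <- switch(treatment_substrate(treatment),
                    nitrate = ambient_no3_at_depth(scenario, depth_m),
                    ammonium = 0)
  tracer <- config_tracer(config, treatment, ambient_umolL = ambient)
  v <- config$liquid_volume_L
  o2 <- o2_at_depth(scenario, depth_m)
  r_lab <- labelled_rate(scenario, treatment, o2)

  t_h <- sort(unique(timepoints_h))
  n0 <- scenario$background_n2o_nM * 2 * v # nmol N2O/L -> nmol N per bottle
  n15_0 <- labeled_n_amount(n0, scenario$background_delta15n_permil, constants)
  n_true <- n0 + r_lab * v * t_h / 24
  n15_true <- n15_0 + r_lab * tracer$f15 * v * t_h / 24

  if (noise$n2o_cv > 0) {
    sdlog <- sqrt(log(1 + noise$n2o_cv^2))
    n_obs <- n_true * stats::rlnorm(length(t_h), -sdlog^2 / 2, sdlog)
  } else {
    n_obs <- n_true
  }
  delta_true <- amount_to_delta(n15_true, n_true, constants)
  if (noise$delta_sigma_permil > 0) {
    delta_obs <- delta_true +
      stats::rnorm(length(t_h), 0, noise$delta_sigma_permil)
  } else {
    delta_obs <- delta_true
  }
  incubation_series(
    station = scenario$station, depth_m = depth_m, treatment = treatment,
    tracer = tracer,
    measurements = data.frame(time_h = t_h, n2o_nmolN = n_obs,
                              delta15n_permil = delta_obs,
                              below_detection = FALSE))
}

#' Simulate a whole station
#'
#' Simulates every (depth, treatment) incubation of a scenario and emits
#' the two tables the analysis stage reads — a hydrographic profile and an
#' incubation table — plus the scenario's ground truth for recovery tests.
#' Deterministic: the same scenario and seed give identical output.
#'
#' @param scenario A [station_scenario()].
#' @param config A `run_config`.
#' @param noise A [noise_model()].
#' @param seed Integer seed for all random draws of this station.
#' @param treatments Treatments to simulate (default all three).
#' @return List with `profile` (station, depth_m, o2_uM, no3_umolL,
#'   nh4_umolL), `incubations` (station, depth_m, treatment, time_h,
#'   n2o_nmolN, delta15n_permil), and `truth` (see [scenario_truth()]).
#' @export
generate_station <- function(scenario, config = default_config(),
                             noise = noise_model(), seed = 1L,
                             treatments = TREATMENTS) {
  if (!inherits(scenario, "station_scenario")) {
    stop_validation("`scenario` must be a station_scenario")
  }
  sim_all <- function() {
    rows <- list()
    for (depth in scenario$depths_m) {
      for (tr in treatments) {
        s <- simulate_incubation(scenario, depth, tr, config, noise,
                                 seed = NULL)
        m <- s$measurements
        rows[[length(rows) + 1L]] <- data.frame(
          station = scenario$station, depth_m = depth, treatment = tr,
          time_h = m$time_h, n2o_nmolN = m$n2o_nmolN,
          delta15n_permil = m$delta15n_permil, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  incubations <- withr::with_seed(as.integer(seed), sim_all())
  profile <- data.frame(
    station = scenario$station,
    depth_m = scenario$depths_m,
    o2_uM = o2_at_depth(scenario, scenario$depths_m),
    no3_umolL = ambient_no3_at_depth(scenario, scenario$depths_m),
    nh4_umolL = 0,
    stringsAsFactors = FALSE
  )
  list(profile = profile, incubations = incubations,
       truth = scenario_truth(scenario, config))
}

#' Write a simulated station to disk
#'
#' Emits `profile.csv` and `incubations.csv` in the exact schemas
#' [read_profile()] and [read_incubations()] expect, plus a
#' `truth.yaml` sidecar with the scenario's true interface depth and
#' integrated fungal fraction for recovery tests.
#'
#' @param station Output of [generate_station()].
#' @param outdir Directory to write into (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_station <- function(station, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(profile = file.path(outdir, "profile.csv"),
             incubations = file.path(outdir, "incubations.csv"),
             truth = file.path(outdir, "truth.yaml"))
  write_table(station$profile, paths[["profile"]])
  write_table(station$incubations, paths[["incubations"]])
  tr <- station$truth
  yaml::write_yaml(list(
    station = tr$profile$station[1],
    z_top_m = tr$z_top_m,
    interface_m = tr$interface_m,
    fungal_fraction_percent = tr$fungal_fraction_percent,
    true_rates = lapply(seq_len(nrow(tr$profile)), function(i)
      as.list(tr$profile[i, c("depth_m", "o2_uM", "fungal_rate",
                              "bacterial_rate", "nitrification_rate")]))
  ), paths[["truth"]])
  invisible(paths)
}
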