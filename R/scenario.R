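# Synthetic station scenarios: the "truth" (pathway rates vs depth and an
# O2 profile) from which incubation experiments are simulated.

PATHWAYS <- c("fungal", "bacterial", "nitrification")

#' Measurement noise model for simulated incubations
#'
#' Gaussian noise on \eqn{\delta^{15}}N with the 2.0 permil precision of a
#' purge-and-trap IRMS, multiplicative lognormal noise on the N\eqn{_2}O
#' quantity (mean-one, so quantities stay unbiased), and the 1.0 nmol N
#' detection limit below which measurements are censored.
#'
#' @param delta_sigma_permil Standard deviation of \eqn{\delta^{15}}N
#'   noise, permil (default 2.0).
#' @param n2o_cv Coefficient of variation of the N\eqn{_2}O quantity
#'   (default 0.02).
#' @param detection_limit_nmolN Detection limit in nmol N (default 1.0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(delta_sigma_permil = 2.0, n2o_cv = 0.02,
                        detection_limit_nmolN = 1.0) {
  vals <- c(delta_sigma_permil, n2o_cv, detection_limit_nmolN)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_validation("noise model parameters must be finite and >= 0")
  }
  structure(list(delta_sigma_permil = delta_sigma_permil, n2o_cv = n2o_cv,
                 detection_limit_nmolN = detection_limit_nmolN),
            class = "noise_model")
}

#' True pathway rate under oxygen inhibition
#'
#' The simulator's oxygen-response model: each pathway produces N\eqn{_2}O
#' at \deqn{R(O_2) = R_{max} \, e^{-O_2 / k_{O_2}}} so production is
#' maximal under anoxia and decays exponentially with in-situ O\eqn{_2}.
#' A larger inhibition constant \eqn{k_{O_2}} means weaker inhibition; the
#' default scenarios give fungal denitrification a larger \eqn{k_{O_2}}
#' than bacterial denitrification, so the fungal share of denitrification
#' rises through the low-oxygen window above the interface.
#'
#' @param pathway `"fungal"`, `"bacterial"` or `"nitrification"`
#'   (informational; the calculation uses `params`).
#' @param o2_uM Dissolved O\eqn{_2} (\eqn{\mu}M), vectorised.
#' @param params List with `r_max` (nmol N L\eqn{^{-1}} d\eqn{^{-1}}) and
#'   `k_o2` (\eqn{\mu}M).
#' @return Rate(s) in nmol N L\eqn{^{-1}} d\eqn{^{-1}}.
#' @examples
#' true_rate("fungal", 2, list(r_max = 10, k_o2 = 2)) # 10/e
#' @export
true_rate <- function(pathway, o2_uM, params) {
  pathway <- match.arg(pathway, PATHWAYS)
  if (is.null(params$r_max) || is.null(params$k_o2) ||
      !is.finite(params$r_max) || params$r_max < 0) {
    stop_validation("pathway params need r_max >= 0 and k_o2 > 0")
  }
  if (!is.finite(params$k_o2) || params$k_o2 <= 0) {
    stop_validation("k_o2 must be > 0")
  }
  if (any(!is.finite(o2_uM)) || any(o2_uM < 0)) {
    stop_validation("o2_uM must be finite and >= 0")
  }
  params$r_max * exp(-o2_uM / params$k_o2)
}

#' Define a synthetic station scenario
#'
#' A scenario is the ground truth from which incubations are simulated: a
#' sampling grid, a sigmoidal oxycline
#' \eqn{O_2(z) = O_2^{surf} / (1 + e^{(z - z_c)/w})}, per-pathway maximum
#' rates and O\eqn{_2} inhibition constants (see [true_rate()]), ambient
#' nitrate, a background N\eqn{_2}O pool, and the residual fraction of
#' prokaryotic activity that chloramphenicol fails to inhibit.
#'
#' @param station Station label.
#' @param depths_m Strictly increasing sampling depths (m).
#' @param o2_surface_uM Surface-side O\eqn{_2} ceiling of the sigmoid
#'   (\eqn{\mu}M).
#' @param oxycline_center_m Depth of the sigmoid midpoint (m).
#' @param oxycline_width_m Sigmoid e-folding width (m, > 0).
#' @param pathways Named list `fungal`/`bacterial`/`nitrification`, each a
#'   list with `r_max` and `k_o2`.
#' @param ambient_no3_umolL Ambient nitrate, a scalar or one value per
#'   depth (\eqn{\mu}mol L\eqn{^{-1}}).
#' @param background_n2o_nM Pre-existing dissolved N\eqn{_2}O (nmol
#'   N\eqn{_2}O L\eqn{^{-1}}; 50 nM is approximately 11.8 nmol N per
#'   0.118 L bottle).
#' @param background_delta15n_permil \eqn{\delta^{15}}N of the background
#'   N\eqn{_2}O.
#' @param cap_leakage_fraction Fraction of bacterial activity that
#'   persists under chloramphenicol (0 = perfect inhibition).
#' @param timepoints_h Sampling times of the incubation end points (h);
#'   must include 0.
#' @param z_top_m Top of the depth-integration window (the oxycline), m.
#' @return An object of class `station_scenario`.
#' @export
station_scenario <- function(station,
                             depths_m,
                             o2_surface_uM,
                             oxycline_center_m,
                             oxycline_width_m,
                             pathways,
                             ambient_no3_umolL = 25,
                             background_n2o_nM = 50,
                             background_delta15n_permil = 0,
                             cap_leakage_fraction = 0,
                             timepoints_h = c(0, 12, 24),
                             z_top_m = min(depths_m)) {
  if (length(depths_m) < 2L || any(diff(depths_m) <= 0)) {
    stop_validation("depths_m must be >= 2 strictly increasing values")
  }
  if (!is.finite(o2_surface_uM) || o2_surface_uM < 0) {
    stop_validation("o2_surface_uM must be >= 0")
  }
  if (!is.finite(oxycline_width_m) || oxycline_width_m <= 0) {
    stop_validation("oxycline_width_m must be > 0")
  }
  if (!setequal(names(pathways), PATHWAYS)) {
    stop_validation("pathways must be named %s", paste(PATHWAYS, collapse = ", "))
  }
  for (p in PATHWAYS) true_rate(p, 0, pathways[[p]]) # validates r_max/k_o2
  if (length(ambient_no3_umolL) == 1L) {
    ambient_no3_umolL <- rep(ambient_no3_umolL, length(depths_m))
  }
  if (length(ambient_no3_umolL) != length(depths_m) ||
      any(!is.finite(ambient_no3_umolL)) || any(ambient_no3_umolL < 0)) {
    stop_validation("ambient_no3_umolL must be >= 0, scalar or one per depth")
  }
  if (!is.finite(background_n2o_nM) || background_n2o_nM <= 0) {
    stop_validation("background_n2o_nM must be > 0")
  }
  if (!is.finite(cap_leakage_fraction) || cap_leakage_fraction < 0 ||
      cap_leakage_fraction > 1) {
    stop_validation("cap_leakage_fraction must lie in [0, 1]")
  }
  if (!(0 %in% timepoints_h) || length(unique(timepoints_h)) < 2L ||
      any(timepoints_h < 0)) {
    stop_validation("timepoints_h must include 0 and >= 2 distinct times")
  }
  if (!is.finite(z_top_m) || z_top_m < min(depths_m)) {
    stop_validation("z_top_m must lie within the sampled depth range")
  }
  structure(list(
    station = station, depths_m = depths_m, o2_surface_uM = o2_surface_uM,
    oxycline_center_m = oxycline_center_m, oxycline_width_m = oxycline_width_m,
    pathways = pathways, ambient_no3_umolL = ambient_no3_umolL,
    background_n2o_nM = background_n2o_nM,
    background_delta15n_permil = background_delta15n_permil,
    cap_leakage_fraction = cap_leakage_fraction,
    timepoints_h = sort(unique(timepoints_h)), z_top_m = z_top_m
  ), class = "station_scenario")
}

#' @export
print.station_scenario <- function(x, ...) {
  cat(sprintf(
    "Station scenario %s: %d depths (%.4g-%.4g m), oxycline %.4g m, CAP leakage %.3g\n",
    x$station, length(x$depths_m), min(x$depths_m), max(x$depths_m),
    x$oxycline_center_m, x$cap_leakage_fraction))
  invisible(x)
}

#' Dissolved oxygen of a scenario at given depths
#'
#' Evaluates the scenario's sigmoidal oxycline; monotone non-increasing in
#' depth and non-negative by construction.
#'
#' @param scenario A [station_scenario()].
#' @param depth_m Depth(s) in metres.
#' @return O\eqn{_2} in \eqn{\mu}M.
#' @export
o2_at_depth <- function(scenario, depth_m) {
  scenario$o2_surface_uM /
    (1 + exp((depth_m - scenario$oxycline_center_m) / scenario$oxycline_width_m))
}

ambient_no3_at_depth <- function(scenario, depth_m) {
  if (length(unique(scenario$ambient_no3_umolL)) == 1L) {
    return(scenario$ambient_no3_umolL[1])
  }
  stats::approx(scenario$depths_m, scenario$ambient_no3_umolL, depth_m,
                rule = 2)$y
}

# Gross labelled production rate seen by one treatment at given O2.
labelled_rate <- function(scenario, treatment, o2) {
  f <- true_rate("fungal", o2, scenario$pathways$fungal)
  b <- true_rate("bacterial", o2, scenario$pathways$bacterial)
  n <- true_rate("nitrification", o2, scenario$pathways$nitrification)
  switch(treatment,
         NO3 = f + b,
         NO3_CAP = f + scenario$cap_leakage_fraction * b,
         NH4 = n,
         stop_validation("unknown treatment '%s'", treatment))
}

#' Ground truth of a scenario
#'
#' Per-depth true pathway rates, the true oxic-anoxic interface depth
#' under the configured threshold, and the true depth-integrated fungal
#' fraction (trapezoid on the sampling grid, like the analysis itself).
#'
#' @param scenario A [station_scenario()].
#' @param config A `run_config` (supplies the O\eqn{_2} threshold).
#' @return List with `profile` (data frame of true rates and O\eqn{_2}),
#'   `interface_m`, `z_top_m`, and `fungal_fraction_percent` (`NA` when
#'   the scenario produces no NO\eqn{_3^-}-fuelled N\eqn{_2}O at all, in
#'   which case [integrate_contribution()] on the truth profile raises).
#' @export
scenario_truth <- function(scenario, config = default_config()) {
  o2 <- o2_at_depth(scenario, scenario$depths_m)
  prof <- data.frame(
    station = scenario$station,
    depth_m = scenario$depths_m,
    o2_uM = o2,
    fungal_rate = true_rate("fungal", o2, scenario$pathways$fungal),
    bacterial_rate = true_rate("bacterial", o2, scenario$pathways$bacterial),
    nitrification_rate = true_rate("nitrification", o2,
                                   scenario$pathways$nitrification),
    stringsAsFactors = FALSE
  )
  prof$total_no3_rate <- prof$fungal_rate + prof$bacterial_rate
  interface <- find_interface(prof$depth_m, prof$o2_uM,
                              config$o2_threshold_uM)
  fraction <- tryCatch(
    integrate_contribution(prof, scenario$z_top_m,
                           interface)$fungal_fraction_percent,
    tracern2o_estimation_error = function(e) NA_real_)
  list(profile = prof, interface_m = interface, z_top_m = scenario$z_top_m,
       fungal_fraction_percent = fraction)
}

#' Default two-station scenarios
#'
#' Two oxygen-minimum-zone stations spanning the oxycline into anoxic
#' depths: station S1 with an end-point (0/24 h) incubation design and a
#' shallow oxycline, station S2 with three time points (0/12/24 h) and a
#' deeper oxycline extending to 275 m. Pathway parameters give bacterial
#' denitrification strong O\eqn{_2} inhibition (k = 1 \eqn{\mu}M) and
#' fungal denitrification weaker inhibition (k = 3 \eqn{\mu}M); the fungal
#' maximum rate is set so that the true depth-integrated fungal share of
#' NO\eqn{_3^-}-fuelled N\eqn{_2}O production between the oxycline and the
#' interface is 20% averaged over the two stations (19.7% at S1, 20.3% at
#' S2).
#'
#' @param cap_leakage_fraction Residual bacterial activity under
#'   chloramphenicol, applied to both stations (default 0).
#' @return Named list of two [station_scenario()] objects.
#' @export
default_scenarios <- function(cap_leakage_fraction = 0) {
  pathways <- list(
    fungal        = list(r_max = 0.726, k_o2 = 3),
    bacterial     = list(r_max = 8,    k_o2 = 1),
    nitrification = list(r_max = 2,    k_o2 = 30)
  )
  list(
    S1 = station_scenario(
      station = "S1",
      depths_m = c(60, 70, 80, 90, 100, 110, 120, 130, 140),
      o2_surface_uM = 200, oxycline_center_m = 75, oxycline_width_m = 6,
      pathways = pathways, ambient_no3_umolL = 25,
      cap_leakage_fraction = cap_leakage_fraction,
      timepoints_h = c(0, 24), z_top_m = 60),
    S2 = station_scenario(
      station = "S2",
      depths_m = c(90, 100, 110, 120, 130, 140, 160, 180, 220, 275),
      o2_surface_uM = 190, oxycline_center_m = 100, oxycline_width_m = 8,
      pathways = pathways, ambient_no3_umolL = 25,
      cap_leakage_fraction = cap_leakage_fraction,
      timepoints_h = c(0, 12, 24), z_top_m = 90)
  )
}
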