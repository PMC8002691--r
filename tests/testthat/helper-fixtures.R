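# Shared fixtures and independent oracles.

# Brute-force OLS slope from the normal equations; independent of lm().
ols_slope_bruteforce <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Fine-grid trapezoidal oracle (1 cm cells, segment knots included),
# summed by hand; independent of pracma.
finegrid_integral <- function(depth, rate, z_top, z_bottom, dz = 0.01) {
  knots <- depth[depth > z_top & depth < z_bottom]
  zz <- sort(unique(c(seq(z_top, z_bottom, by = dz), z_bottom, knots)))
  yy <- approx(depth, rate, zz)$y
  sum(diff(zz) * (head(yy, -1) + tail(yy, -1)) / 2)
}

# A tracer with an arbitrary f15 (via purity, ambient pool excluded).
fixture_tracer <- function(f15 = 0.5, volume_L = 0.118,
                           substrate = "nitrate") {
  compute_label_fraction(substrate, added_nmol = 500, purity_fraction = f15,
                         ambient_umolL = 0, liquid_volume_L = volume_L,
                         include_ambient = FALSE)
}

# Noise-free series whose labelled 15N follows n15_0 + slope * t over the
# given time points, encoded through (n2o, delta) pairs.
fixture_series <- function(slope, n15_0 = 1, times_h = c(0, 12, 24),
                           n2o_nmolN = 12, f15 = 0.5, volume_L = 0.118,
                           station = "S1", depth_m = 100,
                           treatment = "NO3",
                           constants = isotope_constants()) {
  n15 <- n15_0 + slope * times_h
  stopifnot(all(n15 >= 0), all(n15 < n2o_nmolN))
  incubation_series(
    station = station, depth_m = depth_m, treatment = treatment,
    tracer = fixture_tracer(f15, volume_L,
                            substrate = if (treatment == "NH4") "ammonium"
                            else "nitrate"),
    measurements = data.frame(
      time_h = times_h, n2o_nmolN = n2o_nmolN,
      delta15n_permil = amount_to_delta(n15, rep(n2o_nmolN, length(times_h)),
                                        constants)))
}

# A rate_estimate carrying an exact rate value, for partition arithmetic
# tests that must not inherit regression rounding.
fixture_rate <- function(rate, treatment, station = "S1", depth_m = 100) {
  structure(list(station = station, depth_m = depth_m, treatment = treatment,
                 rate_nmolN_L_d = rate, slope_nmol15N_per_h = NA_real_,
                 slope_se = NA_real_, n_points = 3L, p_one_sided = NA_real_,
                 censored_points = 0L, f15 = 0.5, liquid_volume_L = 0.118),
            class = "rate_estimate")
}

# Single-depth scenario with an effectively anoxic deep point, used for
# estimator-recovery experiments.
fixture_scenario <- function(r_fungal = 0.5, r_bact = 5, leakage = 0,
                             timepoints_h = c(0, 12, 24)) {
  station_scenario(
    station = "SX", depths_m = c(60, 200),
    o2_surface_uM = 200, oxycline_center_m = 50, oxycline_width_m = 5,
    pathways = list(fungal = list(r_max = r_fungal, k_o2 = 3),
                    bacterial = list(r_max = r_bact, k_o2 = 1),
                    nitrification = list(r_max = 1, k_o2 = 30)),
    ambient_no3_umolL = 25, cap_leakage_fraction = leakage,
    timepoints_h = timepoints_h, z_top_m = 60)
}
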