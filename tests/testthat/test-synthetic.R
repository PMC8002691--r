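test_that("oxygen inhibition follows the exponential response", {
  prm <- list(r_max = 10, k_o2 = 2)
  expect_equal(true_rate("fungal", 0, prm), 10)
  expect_equal(true_rate("fungal", 2, prm), 10 * exp(-1), tolerance = 1e-12)
  expect_lt(true_rate("fungal", 1e4, prm), 1e-300)
  o2 <- seq(0, 50, by = 0.5)
  expect_true(all(diff(true_rate("bacterial", o2, prm)) <= 0))
  expect_error(true_rate("fungal", 1, list(r_max = 1, k_o2 = 0)),
               class = "tracern2o_validation_error")
  expect_error(true_rate("fungal", -1, prm),
               class = "tracern2o_validation_error")
})

test_that("scenario oxygen profile is monotone and scenarios validate", {
  scen <- default_scenarios()$S1
  z <- seq(0, 300, by = 1)
  o2 <- o2_at_depth(scen, z)
  expect_true(all(o2 >= 0))
  expect_true(all(diff(o2) <= 0))
  expect_error(station_scenario("X", c(100, 90), 200, 75, 6,
                                scen$pathways),
               class = "tracern2o_validation_error") # unsorted depths
  expect_error(station_scenario("X", c(60, 100), 200, 75, 6, scen$pathways,
                                cap_leakage_fraction = 1.5),
               class = "tracern2o_validation_error")
  expect_error(station_scenario("X", c(60, 100), 200, 75, 6, scen$pathways,
                                timepoints_h = c(12, 24)),
               class = "tracern2o_validation_error") # missing t = 0
})

test_that("noise-free simulations round-trip the true rates through fit_rate", {
  scen <- fixture_scenario(r_fungal = 0.5, r_bact = 5)
  quiet <- noise_model(0, 0, 1)
  truth <- scenario_truth(scen)$profile
  tf <- truth$fungal_rate[truth$depth_m == 200]
  tb <- truth$bacterial_rate[truth$depth_m == 200]
  cap <- fit_rate(simulate_incubation(scen, 200, "NO3_CAP", noise = quiet,
                                      seed = 1))
  tot <- fit_rate(simulate_incubation(scen, 200, "NO3", noise = quiet,
                                      seed = 1))
  nh4 <- fit_rate(simulate_incubation(scen, 200, "NH4", noise = quiet,
                                      seed = 1))
  expect_equal(cap$rate_nmolN_L_d, tf, tolerance = 1e-9)
  expect_equal(tot$rate_nmolN_L_d, tf + tb, tolerance = 1e-9)
  expect_equal(tot$rate_nmolN_L_d - cap$rate_nmolN_L_d, tb, tolerance = 1e-9)
  expect_equal(nh4$rate_nmolN_L_d,
               truth$nitrification_rate[truth$depth_m == 200],
               tolerance = 1e-9)
})

test_that("chloramphenicol leakage adds residual bacterial production", {
  leaky <- fixture_scenario(r_fungal = 0.5, r_bact = 5, leakage = 0.3)
  quiet <- noise_model(0, 0, 1)
  truth <- scenario_truth(leaky)$profile
  cap <- fit_rate(simulate_incubation(leaky, 200, "NO3_CAP", noise = quiet,
                                      seed = 1))
  expect_equal(cap$rate_nmolN_L_d,
               truth$fungal_rate[truth$depth_m == 200] +
                 0.3 * truth$bacterial_rate[truth$depth_m == 200],
               tolerance = 1e-9)
})

test_that("simulation is deterministic in the seed and leaves the RNG alone", {
  scen <- default_scenarios()$S2
  a <- simulate_incubation(scen, 140, "NO3", seed = 33)
  b <- simulate_incubation(scen, 140, "NO3", seed = 33)
  expect_identical(a, b)
  c <- simulate_incubation(scen, 140, "NO3", seed = 34)
  expect_false(identical(a$measurements, c$measurements))
  g1 <- generate_station(scen, seed = 5)
  g2 <- generate_station(scen, seed = 5)
  expect_identical(g1, g2)
  # byte-identical files from the same seed
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_station(g1, d1); p2 <- write_station(g2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("scenario truth reports a consistent integrated fraction", {
  for (scen in default_scenarios()) {
    tr <- scenario_truth(scen)
    expect_true(tr$interface_m > min(scen$depths_m) &&
                  tr$interface_m < max(scen$depths_m))
    expect_true(tr$fungal_fraction_percent > 0 &&
                  tr$fungal_fraction_percent < 100)
    # fungal + bacterial add up to the NO3-fuelled total everywhere
    expect_equal(tr$profile$fungal_rate + tr$profile$bacterial_rate,
                 tr$profile$total_no3_rate, tolerance = 1e-12)
  }
})

test_that("an all-quiet scenario yields near-zero rates and an undefined fraction", {
  dead <- station_scenario(
    "S0", c(60, 100, 140, 180), 200, 75, 6,
    pathways = list(fungal = list(r_max = 0, k_o2 = 3),
                    bacterial = list(r_max = 0, k_o2 = 1),
                    nitrification = list(r_max = 0, k_o2 = 30)),
    z_top_m = 60)
  g <- generate_station(dead, noise = noise_model(0, 0, 1), seed = 2)
  ser <- series_from_table(g$incubations, profile = g$profile)
  rates <- rates_table(lapply(ser, fit_rate))
  expect_true(all(abs(rates$rate_nmolN_L_d) < 1e-9))
  expect_true(is.na(g$truth$fungal_fraction_percent))
  expect_error(integrate_contribution(g$truth$profile, 60,
                                      g$truth$interface_m),
               class = "tracern2o_estimation_error")
})
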