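test_that("noise-free three-point series returns the closed-form rate", {
  # 15N2O(t) = 1 + 0.05 t over 0/12/24 h, f15 = 0.5, V = 0.118 L
  s <- fixture_series(slope = 0.05)
  est <- fit_rate(s)
  expect_equal(est$rate_nmolN_L_d, 0.05 * 24 / (0.5 * 0.118),
               tolerance = 1e-9)
  expect_equal(est$rate_nmolN_L_d, 20.33898305, tolerance = 1e-8)
  expect_equal(est$slope_nmol15N_per_h, 0.05, tolerance = 1e-9)
  expect_identical(est$n_points, 3L)
  expect_identical(est$censored_points, 0L)
  # rate = slope * 24 / (f15 V) exactly, by construction
  expect_identical(est$rate_nmolN_L_d,
                   est$slope_nmol15N_per_h * 24 / (est$f15 * est$liquid_volume_L))
})

test_that("constant labelled amount gives a zero rate", {
  s <- fixture_series(slope = 0)
  expect_equal(fit_rate(s)$rate_nmolN_L_d, 0, tolerance = 1e-12)
})

test_that("two-point end-point design yields the difference quotient without inference", {
  s <- fixture_series(slope = 0.05, times_h = c(0, 24))
  est <- fit_rate(s)
  expect_equal(est$rate_nmolN_L_d, 0.05 * 24 / (0.5 * 0.118),
               tolerance = 1e-9)
  expect_true(is.na(est$slope_se))
  expect_true(is.na(est$p_one_sided))
  expect_identical(est$n_points, 2L)
})

test_that("OLS slope matches the brute-force normal equations", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:5, 1)
    t_h <- sort(runif(n, 0, 30))
    n15 <- runif(n, 0.1, 5)
    s <- incubation_series("S1", 100, "NO3", fixture_tracer(),
                           data.frame(time_h = t_h, n2o_nmolN = 12,
                                      delta15n_permil = amount_to_delta(
                                        n15, rep(12, n))))
    est <- fit_rate(s)
    expect_equal(est$slope_nmol15N_per_h, ols_slope_bruteforce(t_h, n15),
                 tolerance = 1e-12)
  }
})

test_that("rates scale with the labelled amounts and inversely with f15", {
  base <- fit_rate(fixture_series(slope = 0.02))$rate_nmolN_L_d
  times3 <- fit_rate(fixture_series(slope = 3 * 0.02, n15_0 = 3))$rate_nmolN_L_d
  expect_equal(times3, 3 * base, tolerance = 1e-9)
  half_f15 <- fit_rate(fixture_series(slope = 0.02, f15 = 0.25))$rate_nmolN_L_d
  expect_equal(half_f15, 2 * base, tolerance = 1e-9)
})

test_that("slope p-value is one-sided and present only with >= 3 points", {
  set.seed(11)
  s <- fixture_series(slope = 0.05, times_h = c(0, 6, 12, 18, 24))
  m <- s$measurements
  m$delta15n_permil <- m$delta15n_permil + rnorm(5, 0, 1)
  s$measurements <- m
  est <- fit_rate(s)
  expect_true(est$p_one_sided > 0 && est$p_one_sided < 0.5) # rising series
  expect_true(is.finite(est$slope_se))
})

test_that("censoring excludes sub-detection points and is reported", {
  s <- fixture_series(slope = 0.05)
  s$measurements$n2o_nmolN <- c(0.5, 12, 12) # first point below 1.0 nmol N
  s$measurements$delta15n_permil[1] <- 0
  cen <- censor_below_detection(s, 1.0)
  expect_identical(cen$measurements$below_detection, c(TRUE, FALSE, FALSE))
  est <- fit_rate(s, detection_limit_nmolN = 1.0)
  expect_identical(est$censored_points, 1L)
  expect_identical(est$n_points, 2L)
  # untouched when everything is above the limit
  s2 <- censor_below_detection(fixture_series(slope = 0.05), 1.0)
  expect_false(any(s2$measurements$below_detection))
})

test_that("unfittable series raise estimation errors", {
  s <- fixture_series(slope = 0.05)
  s$measurements$n2o_nmolN <- rep(0.2, 3) # everything below detection
  expect_error(fit_rate(s, detection_limit_nmolN = 1.0),
               class = "tracern2o_estimation_error")
  s$measurements$n2o_nmolN <- c(0.2, 0.2, 12)
  expect_error(fit_rate(s, detection_limit_nmolN = 1.0),
               class = "tracern2o_estimation_error")
})

test_that("series construction enforces its invariants", {
  m <- data.frame(time_h = c(0, 12, 24), n2o_nmolN = 12, delta15n_permil = 0)
  expect_error(incubation_series("S1", 100, "CAP", fixture_tracer(), m),
               class = "tracern2o_validation_error")
  expect_error(incubation_series("S1", 100, "NH4", fixture_tracer(), m),
               class = "tracern2o_validation_error") # substrate mismatch
  expect_error(incubation_series("S1", 100, "NO3", fixture_tracer(),
                                 m[c(1, 1), ]),
               class = "tracern2o_validation_error") # one distinct time
  m$n2o_nmolN[2] <- -1
  expect_error(incubation_series("S1", 100, "NO3", fixture_tracer(), m),
               class = "tracern2o_validation_error")
})
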