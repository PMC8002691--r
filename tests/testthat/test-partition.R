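test_that("selective-inhibition partition attributes the difference to bacteria", {
  p <- partition_depth(fixture_rate(10, "NO3"), fixture_rate(4, "NO3_CAP"),
                       fixture_rate(1.5, "NH4"), o2_uM = 2)
  expect_equal(p$fungal_rate, 4)
  expect_equal(p$bacterial_rate, 6)
  expect_equal(p$nitrification_rate, 1.5)
  expect_equal(100 * p$fungal_rate / p$total_no3_rate, 40)
  expect_false(p$clamped)
  # zero chloramphenicol rate -> 0% fungal share
  p0 <- partition_depth(fixture_rate(10, "NO3"), fixture_rate(0, "NO3_CAP"))
  expect_equal(p0$fungal_rate, 0)
  expect_equal(p0$bacterial_rate, 10)
  expect_true(p0$nh4_missing)
})

test_that("clamping and flooring flags fire exactly when they should", {
  p <- partition_depth(fixture_rate(10, "NO3"), fixture_rate(12, "NO3_CAP"))
  expect_true(p$clamped)
  expect_equal(p$fungal_rate, 12)
  expect_equal(p$bacterial_rate, 0)
  pneg <- partition_depth(fixture_rate(-0.3, "NO3"), fixture_rate(0.1, "NO3_CAP"))
  expect_true(pneg$floored)
  expect_equal(pneg$total_no3_rate, 0)
  expect_true(pneg$clamped)
  pok <- partition_depth(fixture_rate(5, "NO3"), fixture_rate(2, "NO3_CAP"))
  expect_false(pok$floored)
})

test_that("partition rejects mismatched inputs", {
  expect_error(partition_depth(fixture_rate(10, "NO3"),
                               fixture_rate(4, "NO3_CAP", depth_m = 120)),
               class = "tracern2o_validation_error")
  expect_error(partition_depth(fixture_rate(10, "NO3"),
                               fixture_rate(4, "NO3_CAP", station = "S2")),
               class = "tracern2o_validation_error")
  expect_error(partition_depth(fixture_rate(10, "NO3_CAP"),
                               fixture_rate(4, "NO3")),
               class = "tracern2o_validation_error")
  expect_error(partition_depth(fixture_rate(10, "NO3"),
                               fixture_rate(4, "NO3_CAP"),
                               fixture_rate(1, "NH4", depth_m = 1)),
               class = "tracern2o_validation_error")
})

test_that("interface is interpolated at the first threshold crossing", {
  expect_equal(find_interface(c(60, 90, 120), c(50, 10, 0.5), 1),
               90 + 30 * (10 - 1) / (10 - 0.5), tolerance = 1e-12)
  expect_equal(find_interface(c(60, 90, 120), c(50, 10, 0.5), 1),
               118.4210526, tolerance = 1e-7)
  # already below threshold at the top
  expect_equal(find_interface(c(60, 90), c(0.5, 0.1), 1), 60)
  expect_error(find_interface(c(60, 90, 120), c(50, 20, 10), 1),
               class = "tracern2o_validation_error") # no crossing
  expect_error(find_interface(c(60, 60, 120), c(50, 10, 0.5), 1),
               class = "tracern2o_validation_error") # non-monotone depths
})

test_that("trapezoidal integration matches closed forms", {
  const <- data.frame(depth_m = c(60, 140), fungal_rate = 2,
                      total_no3_rate = 10)
  ic <- integrate_contribution(const, 60, 140)
  expect_equal(ic$integral_fungal, 160)
  expect_equal(ic$integral_total_no3, 800)
  expect_equal(ic$fungal_fraction_percent, 20)
  # linear ramp with fungal = total / 4
  ramp <- data.frame(depth_m = c(60, 140), fungal_rate = c(0, 2.5),
                     total_no3_rate = c(0, 10))
  expect_equal(integrate_contribution(ramp, 60, 140)$fungal_fraction_percent,
               25)
  # clipping interpolates at the bounds
  sub <- integrate_contribution(const, 80, 120)
  expect_equal(sub$integral_fungal, 80)
  expect_equal(sub$fungal_fraction_percent, 20)
})

test_that("integration refuses extrapolation and undefined fractions", {
  prof <- data.frame(depth_m = c(60, 140), fungal_rate = 2,
                     total_no3_rate = 10)
  expect_error(integrate_contribution(prof, 50, 140),
               class = "tracern2o_validation_error")
  expect_error(integrate_contribution(prof, 60, 150),
               class = "tracern2o_validation_error")
  expect_error(integrate_contribution(prof, 140, 60),
               class = "tracern2o_validation_error")
  zero <- data.frame(depth_m = c(60, 140), fungal_rate = 0,
                     total_no3_rate = 0)
  expect_error(integrate_contribution(zero, 60, 140),
               class = "tracern2o_estimation_error")
})

test_that("source conservation holds whenever no clamp fires", {
  set.seed(21)
  for (i in 1:50) {
    tot <- runif(1, 0, 10)
    cap <- runif(1, 0, tot)
    p <- partition_depth(fixture_rate(tot, "NO3"), fixture_rate(cap, "NO3_CAP"))
    expect_false(p$clamped)
    expect_identical(p$fungal_rate + p$bacterial_rate, p$total_no3_rate)
  }
})
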