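# Source partitioning by selective inhibition, interface location, and
# depth integration of the fungal share.

#' Partition N2O production at one depth into sources
#'
#' The chloramphenicol treatment (`NO3_CAP`) inhibits prokaryotic protein
#' synthesis, so its rate approximates fungal denitrification (an upper
#' limit if inhibition is incomplete); the difference between the plain
#' \eqn{^{15}}NO\eqn{_3^-} rate and the chloramphenicol rate is attributed
#' to bacterial denitrification, and the \eqn{^{15}}NH\eqn{_4^+} rate to
#' archaeal/bacterial nitrification. Negative input rates (regression noise
#' at near-zero production) are floored at zero before partitioning; if the
#' chloramphenicol rate exceeds the total, the bacterial rate is clamped to
#' zero and the profile flagged.
#'
#' @param total `rate_estimate` from the `NO3` treatment.
#' @param cap `rate_estimate` from the `NO3_CAP` treatment at the same
#'   station and depth.
#' @param nh4 Optional `rate_estimate` from the `NH4` treatment; if absent
#'   the nitrification rate is 0 and `nh4_missing` is set.
#' @param o2_uM In-situ dissolved O\eqn{_2} at this depth (\eqn{\mu}M), for
#'   reporting.
#' @return An object of class `partitioned_profile`.
#' @examples
#' # see partition_table() for assembling a whole profile
#' @export
partition_depth <- function(total, cap, nh4 = NULL, o2_uM = NA_real_) {
  for (x in list(total, cap)) {
    if (!inherits(x, "rate_estimate")) {
      stop_validation("`total` and `cap` must be rate_estimate objects")
    }
  }
  if (total$treatment != "NO3" || cap$treatment != "NO3_CAP") {
    stop_validation("expected treatments NO3 (total) and NO3_CAP (cap), got %s and %s",
                    total$treatment, cap$treatment)
  }
  if (!identical(total$station, cap$station) || total$depth_m != cap$depth_m) {
    stop_validation("total and cap estimates are from different station/depth")
  }
  floored <- FALSE
  floor0 <- function(r) {
    if (r < 0) {
      floored <<- TRUE
      0
    } else r
  }
  total_rate <- floor0(total$rate_nmolN_L_d)
  fungal <- floor0(cap$rate_nmolN_L_d)
  nh4_missing <- is.null(nh4)
  if (nh4_missing) {
    nitrif <- 0
  } else {
    if (!inherits(nh4, "rate_estimate") || nh4$treatment != "NH4") {
      stop_validation("`nh4` must be a rate_estimate for treatment NH4")
    }
    if (!identical(nh4$station, total$station) || nh4$depth_m != total$depth_m) {
      stop_validation("nh4 estimate is from a different station/depth")
    }
    nitrif <- floor0(nh4$rate_nmolN_L_d)
  }
  clamped <- fungal > total_rate
  bacterial <- max(total_rate - fungal, 0)
  structure(list(
    station = total$station,
    depth_m = total$depth_m,
    o2_uM = o2_uM,
    total_no3_rate = total_rate,
    fungal_rate = fungal,
    bacterial_rate = bacterial,
    nitrification_rate = nitrif,
    clamped = clamped,
    floored = floored,
    nh4_missing = nh4_missing
  ), class = "partitioned_profile")
}

#' @export
print.partitioned_profile <- function(x, ...) {
  cat(sprintf(
    "Partition: station %s, %.4g m (O2 %.3g uM): total %.4g = fungal %.4g + bacterial %.4g; nitrification %.4g%s\n",
    x$station, x$depth_m, x$o2_uM, x$total_no3_rate, x$fungal_rate,
    x$bacterial_rate, x$nitrification_rate,
    if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' @export
as.data.frame.partitioned_profile <- function(x, ...) {
  data.frame(station = x$station, depth_m = x$depth_m, o2_uM = x$o2_uM,
             total_no3_rate = x$total_no3_rate, fungal_rate = x$fungal_rate,
             bacterial_rate = x$bacterial_rate,
             nitrification_rate = x$nitrification_rate, clamped = x$clamped,
             floored = x$floored, nh4_missing = x$nh4_missing,
             stringsAsFactors = FALSE)
}

#' Collect partitioned depths into a profile table
#'
#' @param partitions List of `partitioned_profile` objects.
#' @return Data frame sorted by station then depth.
#' @export
partition_table <- function(partitions) {
  df <- do.call(rbind, lapply(partitions, as.data.frame))
  df <- df[order(df$station, df$depth_m), ]
  rownames(df) <- NULL
  df
}

#' Locate the oxic-anoxic interface in an O2 profile
#'
#' Returns the shallowest depth at which dissolved O\eqn{_2} first falls
#' below the threshold, linearly interpolated between the bracketing
#' sampled depths. The default threshold of 1.0 \eqn{\mu}M sits inside the
#' low-oxygen niche where denitrification becomes active; it is exposed
#' because oxygen-sensor floors differ between instruments.
#'
#' @param depth_m Strictly increasing depths (m).
#' @param o2_uM Dissolved O\eqn{_2} at those depths (\eqn{\mu}M).
#' @param threshold_uM Interface threshold (\eqn{\mu}M), default 1.0.
#' @return Interface depth in metres.
#' @examples
#' find_interface(c(60, 90, 120), c(50, 10, 0.5)) # 118.42 m
#' @export
find_interface <- function(depth_m, o2_uM, threshold_uM = 1.0) {
  if (length(depth_m) < 2L || length(depth_m) != length(o2_uM)) {
    stop_validation("need >= 2 (depth, O2) pairs of equal length")
  }
  if (any(diff(depth_m) <= 0)) {
    stop_validation("depths must be strictly increasing")
  }
  if (any(!is.finite(o2_uM)) || any(o2_uM < 0)) {
    stop_validation("O2 values must be finite and >= 0")
  }
  if (o2_uM[1] < threshold_uM) {
    return(depth_m[1])
  }
  below <- which(o2_uM < threshold_uM)
  if (length(below) == 0L) {
    stop_validation("O2 never falls below %.3g uM within the profile (min %.3g uM)",
                    threshold_uM, min(o2_uM))
  }
  i <- below[1]
  depth_m[i - 1] + (depth_m[i] - depth_m[i - 1]) *
    (o2_uM[i - 1] - threshold_uM) / (o2_uM[i - 1] - o2_uM[i])
}

#' Depth-integrate the fungal contribution to N2O production
#'
#' Trapezoidal integration of the fungal and total
#' \eqn{^{15}}NO\eqn{_3^-}-based rates between two depths (typically the
#' oxycline and the oxic-anoxic interface), with linear interpolation of
#' the rates at the clip boundaries. Volumetric rates in
#' nmol N L\eqn{^{-1}} d\eqn{^{-1}} integrated over metres give areal
#' rates in \eqn{\mu}mol N m\eqn{^{-2}} d\eqn{^{-1}} (factor 1).
#' Extrapolation beyond the sampled depth range is refused.
#'
#' @param partition Data frame with columns `depth_m`, `fungal_rate`,
#'   `total_no3_rate` (one station; see [partition_table()]).
#' @param z_top_m,z_bottom_m Integration bounds in metres,
#'   `z_top_m < z_bottom_m`, both inside the sampled depth range.
#' @return An object of class `integrated_contribution` with the two areal
#'   integrals and `fungal_fraction_percent`.
#' @examples
#' prof <- data.frame(depth_m = c(60, 140), fungal_rate = 2,
#'                    total_no3_rate = 10)
#' integrate_contribution(prof, 60, 140) # 20% fungal
#' @export
integrate_contribution <- function(partition, z_top_m, z_bottom_m) {
  req <- c("depth_m", "fungal_rate", "total_no3_rate")
  if (!is.data.frame(partition) || !all(req %in% names(partition))) {
    stop_validation("`partition` needs columns %s", paste(req, collapse = ", "))
  }
  if (!is.finite(z_top_m) || !is.finite(z_bottom_m) || z_top_m >= z_bottom_m) {
    stop_validation("need z_top_m < z_bottom_m")
  }
  p <- partition[order(partition$depth_m), ]
  if (any(duplicated(p$depth_m))) {
    stop_validation("duplicate depths in partition profile")
  }
  if (nrow(p) < 2L) stop_validation("need >= 2 depths to integrate")
  if (z_top_m < min(p$depth_m) || z_bottom_m > max(p$depth_m)) {
    stop_validation(
      "integration bounds [%.4g, %.4g] m exceed the sampled range [%.4g, %.4g] m; extrapolation is refused",
      z_top_m, z_bottom_m, min(p$depth_m), max(p$depth_m))
  }
  zz <- sort(unique(c(z_top_m, z_bottom_m,
                      p$depth_m[p$depth_m > z_top_m & p$depth_m < z_bottom_m])))
  fz <- stats::approx(p$depth_m, p$fungal_rate, zz)$y
  tz <- stats::approx(p$depth_m, p$total_no3_rate, zz)$y
  int_f <- pracma::trapz(zz, fz)
  int_t <- pracma::trapz(zz, tz)
  if (int_t == 0) {
    stop_estimation("total NO3-based integral is zero; fungal fraction undefined")
  }
  structure(list(
    station = if ("station" %in% names(p)) p$station[1] else NA_character_,
    z_top_m = z_top_m,
    z_bottom_m = z_bottom_m,
    integral_fungal = int_f,
    integral_total_no3 = int_t,
    fungal_fraction_percent = 100 * int_f / int_t
  ), class = "integrated_contribution")
}

#' @export
print.integrated_contribution <- function(x, ...) {
  cat(sprintf(
    "Integrated %.4g-%.4g m: fungal %.4g / total %.4g umol N/m2/d = %.3g%% fungal\n",
    x$z_top_m, x$z_bottom_m, x$integral_fungal, x$integral_total_no3,
    x$fungal_fraction_percent))
  invisible(x)
}

#' @export
as.data.frame.integrated_contribution <- function(x, ...) {
  data.frame(station = x$station, z_top_m = x$z_top_m,
             z_bottom_m = x$z_bottom_m, integral_fungal = x$integral_fungal,
             integral_total_no3 = x$integral_total_no3,
             fungal_fraction_percent = x$fungal_fraction_percent,
             stringsAsFactors = FALSE)
}
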