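# Volumetric N2O production rates from 15N2O time series:
#   R_N2O = (d15N2O/dt) / (f15 x V)
# with d15N2O/dt the OLS slope of labelled nmol 15N against time.

#' Fit a volumetric N2O production rate to a tracer time series
#'
#' Each measurement is converted to nmol \eqn{^{15}}N with
#' [labeled_n_amount()]; the production slope is the ordinary least-squares
#' slope of \eqn{^{15}}N\eqn{_2}O against time (h), and the volumetric rate
#' is \deqn{R_{N_2O} = \frac{d^{15}N_2O/dt}{f^{15} \times V} \times 24}
#' in nmol N L\eqn{^{-1}} d\eqn{^{-1}}. Two-point series (the 0/24 h
#' end-point design) yield the difference quotient with no standard error
#' or p-value; series with three or more usable points also report the
#' slope standard error and a one-sided p-value for slope > 0.
#'
#' @param series An [incubation_series()].
#' @param constants An [isotope_constants()] object.
#' @param detection_limit_nmolN If non-`NULL`, [censor_below_detection()]
#'   is applied first with this limit.
#' @return An object of class `rate_estimate`.
#' @examples
#' tr <- compute_label_fraction("nitrate", 500, 0.99, 0, 0.118)
#' m <- data.frame(time_h = c(0, 12, 24), n2o_nmolN = 12,
#'                 delta15n_permil = c(0, 500, 1000))
#' fit_rate(incubation_series("S1", 100, "NO3", tr, m))
#' @export
fit_rate <- function(series, constants = isotope_constants(),
                     detection_limit_nmolN = NULL) {
  if (!inherits(series, "incubation_series")) {
    stop_validation("`series` must be an incubation_series")
  }
  if (!is.null(detection_limit_nmolN)) {
    series <- censor_below_detection(series, detection_limit_nmolN)
  }
  m <- series$measurements
  usable <- m[!m$below_detection, , drop = FALSE]
  censored <- sum(m$below_detection)
  if (nrow(usable) < 2L || length(unique(usable$time_h)) < 2L) {
    stop_estimation(
      "cannot fit rate at station %s depth %s (%s): %d usable point(s) after censoring",
      series$station, format(series$depth_m), series$treatment, nrow(usable))
  }
  n15 <- labeled_n_amount(usable$n2o_nmolN, usable$delta15n_permil, constants)
  t_h <- usable$time_h
  if (nrow(usable) == 2L) {
    slope <- diff(n15) / diff(t_h)
    slope_se <- NA_real_
    p_one <- NA_real_
  } else {
    fit <- stats::lm(n15 ~ t_h)
    # suppress summary.lm's "essentially perfect fit" warning: noise-free
    # simulated series legitimately have zero residuals
    cf <- suppressWarnings(summary(fit))$coefficients
    slope <- cf["t_h", "Estimate"]
    slope_se <- cf["t_h", "Std. Error"]
    p_one <- stats::pt(cf["t_h", "t value"], df = fit$df.residual,
                       lower.tail = FALSE)
  }
  f15 <- series$tracer$f15
  v <- series$tracer$liquid_volume_L
  if (!is.finite(f15) || f15 <= 0) stop_validation("tracer f15 must be > 0")
  structure(list(
    station = series$station,
    depth_m = series$depth_m,
    treatment = series$treatment,
    rate_nmolN_L_d = slope * 24 / (f15 * v),
    slope_nmol15N_per_h = slope,
    slope_se = slope_se,
    n_points = nrow(usable),
    p_one_sided = p_one,
    censored_points = censored,
    f15 = f15,
    liquid_volume_L = v
  ), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "Rate: station %s, %.4g m, %s: %.4g nmol N/L/d (slope %.4g nmol 15N/h, n = %d%s)\n",
    x$station, x$depth_m, x$treatment, x$rate_nmolN_L_d,
    x$slope_nmol15N_per_h, x$n_points,
    if (is.na(x$p_one_sided)) "" else sprintf(", p = %.3g", x$p_one_sided)))
  invisible(x)
}

#' @export
as.data.frame.rate_estimate <- function(x, ...) {
  data.frame(station = x$station, depth_m = x$depth_m, treatment = x$treatment,
             rate_nmolN_L_d = x$rate_nmolN_L_d, slope_se = x$slope_se,
             n_points = x$n_points, p_one_sided = x$p_one_sided,
             censored_points = x$censored_points,
             stringsAsFactors = FALSE)
}

#' Collect rate estimates into a table
#'
#' @param estimates List of `rate_estimate` objects.
#' @return Data frame, one row per estimate, ordered by station, depth,
#'   treatment.
#' @export
rates_table <- function(estimates) {
  df <- do.call(rbind, lapply(estimates, as.data.frame))
  df <- df[order(df$station, df$depth_m, match(df$treatment, TREATMENTS)), ]
  rownames(df) <- NULL
  df
}
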