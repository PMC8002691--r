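# Incubation time series: one bottle set (station, depth, treatment) with
# its tracer and ordered measurements.

TREATMENTS <- c("NO3", "NO3_CAP", "NH4")

treatment_substrate <- function(treatment) {
  switch(treatment, NO3 = "nitrate", NO3_CAP = "nitrate", NH4 = "ammonium",
         stop_validation("unknown treatment '%s'; allowed: %s", treatment,
                         paste(TREATMENTS, collapse = ", ")))
}

#' Construct an incubation time series
#'
#' One series holds all time points of a parallel-incubation set for a
#' single station, depth and treatment, together with the tracer that was
#' added. Treatments: `NO3` (\eqn{^{15}}NO\eqn{_3^-} only), `NO3_CAP`
#' (\eqn{^{15}}NO\eqn{_3^-} plus chloramphenicol) and `NH4`
#' (\eqn{^{15}}NH\eqn{_4^+}).
#'
#' @param station Station label.
#' @param depth_m Depth in metres, positive downward.
#' @param treatment One of `"NO3"`, `"NO3_CAP"`, `"NH4"`.
#' @param tracer A `tracer_spec` from [compute_label_fraction()]; its
#'   substrate must match the treatment.
#' @param measurements Data frame with columns `time_h`, `n2o_nmolN`,
#'   `delta15n_permil` and optionally `below_detection`.
#' @return An object of class `incubation_series`.
#' @export
incubation_series <- function(station, depth_m, treatment, tracer,
                              measurements) {
  if (!treatment %in% TREATMENTS) {
    stop_validation("treatment '%s' invalid; allowed: %s", treatment,
                    paste(TREATMENTS, collapse = ", "))
  }
  if (!inherits(tracer, "tracer_spec")) {
    stop_validation("`tracer` must be a tracer_spec")
  }
  if (tracer$substrate != treatment_substrate(treatment)) {
    stop_validation("treatment %s requires a %s tracer, got %s", treatment,
                    treatment_substrate(treatment), tracer$substrate)
  }
  req <- c("time_h", "n2o_nmolN", "delta15n_permil")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements))) {
    stop_validation("`measurements` needs columns %s",
                    paste(req, collapse = ", "))
  }
  m <- measurements[order(measurements$time_h),
                    c(req, intersect("below_detection", names(measurements)))]
  if (is.null(m$below_detection)) m$below_detection <- FALSE
  rownames(m) <- NULL
  if (any(!is.finite(m$time_h)) || any(m$time_h < 0)) {
    stop_validation("time_h must be finite and >= 0")
  }
  if (any(!is.finite(m$n2o_nmolN)) || any(m$n2o_nmolN < 0)) {
    stop_validation("n2o_nmolN must be finite and >= 0")
  }
  if (any(m$delta15n_permil <= -1000)) {
    stop_validation("delta15n_permil must be > -1000 permil")
  }
  if (length(unique(m$time_h)) < 2L) {
    stop_validation("series needs >= 2 measurements at distinct times")
  }
  structure(list(station = station, depth_m = depth_m, treatment = treatment,
                 tracer = tracer, measurements = m),
            class = "incubation_series")
}

#' @export
print.incubation_series <- function(x, ...) {
  cat(sprintf("Incubation series: station %s, %.4g m, %s (f15 = %.4g), %d time points\n",
              x$station, x$depth_m, x$treatment, x$tracer$f15,
              nrow(x$measurements)))
  print(x$measurements)
  invisible(x)
}

#' Flag measurements below the instrument detection limit
#'
#' Measurements whose total N\eqn{_2}O quantity falls below the detection
#' limit (1.0 nmol N for the purge-and-trap IRMS setup this models) are
#' flagged `below_detection`; [fit_rate()] excludes flagged points from the
#' regression and reports how many were censored.
#'
#' @param series An [incubation_series()].
#' @param detection_limit_nmolN Detection limit in nmol N (>= 0).
#' @return The series with `below_detection` flags updated.
#' @export
censor_below_detection <- function(series, detection_limit_nmolN = 1.0) {
  if (!inherits(series, "incubation_series")) {
    stop_validation("`series` must be an incubation_series")
  }
  if (!is.finite(detection_limit_nmolN) || detection_limit_nmolN < 0) {
    stop_validation("`detection_limit_nmolN` must be >= 0")
  }
  series$measurements$below_detection <-
    series$measurements$n2o_nmolN < detection_limit_nmolN
  series
}
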