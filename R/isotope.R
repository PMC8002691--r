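# Delta-notation arithmetic for 15N and conversion of bulk d15N-N2O plus
# N2O quantity into nmol of labelled 15N.

#' Isotope reference constants
#'
#' Bundles the two isotope ratios the pipeline needs: the ratio of the
#' working reference gas against which sample \eqn{\delta^{15}}N values are
#' expressed, and the \eqn{^{15}}N/\eqn{^{14}}N ratio of atmospheric
#' N\eqn{_2} (AIR) used for the natural abundance of ambient substrate
#' pools. Both default to the AIR standard, 0.0036765, because AIR is the
#' universal reference for \eqn{\delta^{15}}N; either can be overridden for
#' instruments calibrated against a different working gas.
#'
#' @param r_ref Isotope ratio of the reference gas (dimensionless).
#' @param r_air \eqn{^{15}}N/\eqn{^{14}}N of atmospheric N\eqn{_2}.
#' @return An object of class `isotope_constants`.
#' @examples
#' isotope_constants()
#' @export
isotope_constants <- function(r_ref = 0.0036765, r_air = 0.0036765) {
  if (!is.numeric(r_ref) || length(r_ref) != 1L || !is.finite(r_ref) ||
      r_ref <= 0 || r_ref >= 0.05) {
    stop_validation("`r_ref` must be a single ratio in (0, 0.05)")
  }
  if (!is.numeric(r_air) || length(r_air) != 1L || !is.finite(r_air) ||
      r_air <= 0 || r_air >= 0.05) {
    stop_validation("`r_air` must be a single ratio in (0, 0.05)")
  }
  structure(list(r_ref = r_ref, r_air = r_air), class = "isotope_constants")
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("Isotope constants: R_ref =", format(x$r_ref, digits = 8),
      " R_air =", format(x$r_air, digits = 8), "\n")
  invisible(x)
}

#' Convert delta notation to an isotope ratio
#'
#' \eqn{R = R_{std} (\delta/1000 + 1)}. Values of \eqn{\delta \le -1000}
#' permil would imply a non-positive ratio and are rejected.
#'
#' @param delta_permil Delta value(s) in permil.
#' @param r_std Reference ratio (positive scalar).
#' @return Isotope ratio(s), same length as `delta_permil`.
#' @examples
#' delta_to_ratio(0, 0.0036765)
#' @export
delta_to_ratio <- function(delta_permil, r_std) {
  if (!is.numeric(r_std) || length(r_std) != 1L || r_std <= 0) {
    stop_validation("`r_std` must be a single positive ratio")
  }
  if (any(!is.finite(delta_permil)) || any(delta_permil <= -1000)) {
    stop_validation("delta values must be finite and > -1000 permil")
  }
  r_std * (delta_permil / 1000 + 1)
}

#' Convert an isotope ratio to an atom fraction
#'
#' \eqn{f = R / (1 + R)}, the fraction of N atoms that are \eqn{^{15}}N.
#'
#' @param r Isotope ratio(s), non-negative.
#' @return Atom fraction(s) in \[0, 1).
#' @export
ratio_to_atom_fraction <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) {
    stop_validation("isotope ratios must be finite and >= 0")
  }
  r / (1 + r)
}

#' Convert an atom fraction to an isotope ratio
#'
#' Inverse of [ratio_to_atom_fraction()]: \eqn{R = f / (1 - f)}.
#'
#' @param f Atom fraction(s) in \[0, 1).
#' @return Isotope ratio(s).
#' @export
atom_fraction_to_ratio <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1)) {
    stop_validation("atom fractions must lie in [0, 1)")
  }
  f / (1 - f)
}

#' Labelled nitrogen in a measured N2O pool
#'
#' Converts a bulk \eqn{\delta^{15}}N-N\eqn{_2}O and the total N\eqn{_2}O
#' quantity (expressed as nmol of N atoms) into nmol of \eqn{^{15}}N:
#' \deqn{^{15}N_2O = N_2O \times
#'   \frac{(\delta/1000 + 1) R_{ref}}{1 + (\delta/1000 + 1) R_{ref}}}
#' The result is the quantity regressed against time to obtain a
#' production rate.
#'
#' @param n2o_nmolN Total N\eqn{_2}O quantity in nmol N (vectorised).
#' @param delta15n_permil Bulk \eqn{\delta^{15}}N of the N\eqn{_2}O, permil.
#' @param constants An [isotope_constants()] object.
#' @return nmol of \eqn{^{15}}N, in \[0, `n2o_nmolN`).
#' @examples
#' labeled_n_amount(100, 0) # 0.3663 nmol 15N at natural abundance
#' @export
labeled_n_amount <- function(n2o_nmolN, delta15n_permil,
                             constants = isotope_constants()) {
  if (any(!is.finite(n2o_nmolN)) || any(n2o_nmolN < 0)) {
    stop_validation("`n2o_nmolN` must be finite and >= 0")
  }
  af <- ratio_to_atom_fraction(delta_to_ratio(delta15n_permil, constants$r_ref))
  n2o_nmolN * af
}

#' Delta value implied by a labelled amount
#'
#' Exact inverse of [labeled_n_amount()]: given nmol of \eqn{^{15}}N inside
#' a total pool of nmol N, returns the bulk \eqn{\delta^{15}}N in permil.
#' Used by the incubation simulator to translate true labelled amounts into
#' the delta values an isotope-ratio mass spectrometer would report.
#'
#' @param n15_nmol nmol of \eqn{^{15}}N; must satisfy
#'   `0 <= n15_nmol < n2o_nmolN`.
#' @param n2o_nmolN Total pool in nmol N (positive).
#' @param constants An [isotope_constants()] object.
#' @return \eqn{\delta^{15}}N in permil.
#' @export
amount_to_delta <- function(n15_nmol, n2o_nmolN,
                            constants = isotope_constants()) {
  if (any(!is.finite(n15_nmol)) || any(!is.finite(n2o_nmolN)) ||
      any(n2o_nmolN <= 0) || any(n15_nmol < 0) || any(n15_nmol >= n2o_nmolN)) {
    stop_validation("need 0 <= n15_nmol < n2o_nmolN with n2o_nmolN > 0")
  }
  r <- atom_fraction_to_ratio(n15_nmol / n2o_nmolN)
  (r / constants$r_ref - 1) * 1000
}

#' Atom fraction of the labelled substrate pool
#'
#' Computes \eqn{f^{15}}, the atom fraction \eqn{^{15}}N of the total
#' substrate pool in an incubation bottle after tracer addition, as the
#' amount-weighted mean of the tracer purity and the natural abundance of
#' the ambient pool:
#' \deqn{f^{15} = \frac{n_{add} p + n_{amb} f_{air}}{n_{add} + n_{amb}}}
#' with \eqn{n_{amb} =} `ambient_umolL` \eqn{\times V \times 1000} nmol and
#' \eqn{f_{air} = r_{air}/(1+r_{air})}. Ambient concentrations below the
#' analytical detection limit for the substrate are treated as zero, with a
#' warning. Set `include_ambient = FALSE` to use the tracer purity alone
#' (i.e. ignore dilution by the ambient pool).
#'
#' @param substrate `"nitrate"` or `"ammonium"`.
#' @param added_nmol nmol of tracer N added to the bottle.
#' @param purity_fraction Atom fraction \eqn{^{15}}N of the tracer (0, 1\].
#' @param ambient_umolL Ambient concentration of the same substrate,
#'   \eqn{\mu}mol L\eqn{^{-1}}.
#' @param liquid_volume_L Incubation liquid volume in litres.
#' @param constants An [isotope_constants()] object.
#' @param include_ambient Include the ambient pool in the mixing
#'   calculation (default `TRUE`).
#' @param ambient_detection_umolL Detection limit below which the ambient
#'   concentration is treated as zero; defaults to 0.2 \eqn{\mu}M for
#'   nitrate and 0.015 \eqn{\mu}M for ammonium.
#' @return An object of class `tracer_spec` with the derived `f15`.
#' @examples
#' compute_label_fraction("nitrate", 500, 0.99, ambient_umolL = 20,
#'                        liquid_volume_L = 0.118)
#' @export
compute_label_fraction <- function(substrate = c("nitrate", "ammonium"),
                                   added_nmol, purity_fraction,
                                   ambient_umolL = 0,
                                   liquid_volume_L = 0.118,
                                   constants = isotope_constants(),
                                   include_ambient = TRUE,
                                   ambient_detection_umolL = NULL) {
  substrate <- match.arg(substrate)
  if (!is.finite(added_nmol) || added_nmol < 0) {
    stop_validation("`added_nmol` must be finite and >= 0")
  }
  if (!is.finite(purity_fraction) || purity_fraction <= 0 ||
      purity_fraction > 1) {
    stop_validation("`purity_fraction` must lie in (0, 1]")
  }
  if (!is.finite(liquid_volume_L) || liquid_volume_L <= 0) {
    stop_validation("`liquid_volume_L` must be positive")
  }
  if (!is.finite(ambient_umolL) || ambient_umolL < 0) {
    stop_validation("`ambient_umolL` must be finite and >= 0")
  }
  if (is.null(ambient_detection_umolL)) {
    ambient_detection_umolL <-
      switch(substrate, nitrate = 0.2, ammonium = 0.015)
  }
  if (ambient_umolL > 0 && ambient_umolL < ambient_detection_umolL) {
    warning(sprintf(
      "ambient %s %.4g umol/L is below the %.4g umol/L detection limit; treated as 0",
      substrate, ambient_umolL, ambient_detection_umolL))
    ambient_umolL <- 0
  }
  ambient_nmol <- ambient_umolL * liquid_volume_L * 1000
  if (!include_ambient) {
    f15 <- purity_fraction
  } else {
    if (added_nmol + ambient_nmol == 0) {
      stop_validation("no substrate pool: added_nmol + ambient pool is zero")
    }
    natural <- ratio_to_atom_fraction(constants$r_air)
    f15 <- (added_nmol * purity_fraction + ambient_nmol * natural) /
      (added_nmol + ambient_nmol)
  }
  structure(list(
    substrate = substrate,
    added_nmol = added_nmol,
    purity_fraction = purity_fraction,
    ambient_umolL = ambient_umolL,
    liquid_volume_L = liquid_volume_L,
    f15 = f15
  ), class = "tracer_spec")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf(
    "Tracer: %s, %.4g nmol 15N at purity %.3g, ambient %.4g umol/L, V = %.4g L, f15 = %.6g\n",
    x$substrate, x$added_nmol, x$purity_fraction, x$ambient_umolL,
    x$liquid_volume_L, x$f15))
  invisible(x)
}
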