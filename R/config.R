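# Run configuration: isotope constants, tracer additions per treatment,
# detection limits, and interface/integration settings. YAML-backed.

#' Default run configuration
#'
#' Encodes the incubation design this pipeline models: 120 mL serum
#' bottles with 2 mL helium headspace (0.118 L of seawater), tracer
#' additions of 0.1 mL of 5 mM 99%-pure \eqn{^{15}}NO\eqn{_3^-} (500 nmol
#' \eqn{^{15}}N) or 0.1 mL of 0.8 mM 99%-pure \eqn{^{15}}NH\eqn{_4^+}
#' (80 nmol), a 1.0 nmol N instrument detection limit, and a 1.0
#' \eqn{\mu}M O\eqn{_2} threshold for the oxic-anoxic interface.
#'
#' @param ... Named overrides of the default fields; unknown names are
#'   rejected.
#' @return An object of class `run_config`.
#' @examples
#' default_config(o2_threshold_uM = 0.5)
#' @export
default_config <- function(...) {
  cfg <- list(
    r_ref = 0.0036765,
    r_air = 0.0036765,
    liquid_volume_L = 0.118,
    tracers = list(
      NO3     = list(added_nmol = 500, purity_fraction = 0.99),
      NO3_CAP = list(added_nmol = 500, purity_fraction = 0.99),
      NH4     = list(added_nmol = 80,  purity_fraction = 0.99)
    ),
    include_ambient_in_f15 = TRUE,
    detection_limit_nmolN = 1.0,
    o2_threshold_uM = 1.0
  )
  validate_config(modify_config(cfg, list(...)))
}

modify_config <- function(cfg, updates) {
  if (length(updates) == 0L) return(cfg)
  nm <- names(updates)
  if (is.null(nm) || any(nm == "")) {
    stop_validation("config overrides must be named")
  }
  unknown <- setdiff(nm, names(cfg))
  if (length(unknown) > 0L) {
    stop_validation("unknown config key(s): %s (allowed: %s)",
                    paste(unknown, collapse = ", "),
                    paste(names(cfg), collapse = ", "))
  }
  for (k in nm) {
    if (k == "tracers") {
      bad <- setdiff(names(updates$tracers), TREATMENTS)
      if (length(bad) > 0L) {
        stop_validation("unknown tracer treatment(s): %s",
                        paste(bad, collapse = ", "))
      }
      for (tr in names(updates$tracers)) {
        cfg$tracers[[tr]] <- utils::modifyList(cfg$tracers[[tr]],
                                               updates$tracers[[tr]])
      }
    } else {
      cfg[[k]] <- updates[[k]]
    }
  }
  cfg
}

validate_config <- function(cfg) {
  isotope_constants(cfg$r_ref, cfg$r_air) # reuses its range checks
  if (!is.finite(cfg$liquid_volume_L) || cfg$liquid_volume_L <= 0) {
    stop_validation("liquid_volume_L must be positive")
  }
  for (tr in TREATMENTS) {
    t <- cfg$tracers[[tr]]
    if (is.null(t) || !is.finite(t$added_nmol) || t$added_nmol < 0 ||
        !is.finite(t$purity_fraction) || t$purity_fraction <= 0 ||
        t$purity_fraction > 1) {
      stop_validation("tracer spec for %s invalid", tr)
    }
  }
  if (!is.finite(cfg$detection_limit_nmolN) || cfg$detection_limit_nmolN < 0) {
    stop_validation("detection_limit_nmolN must be >= 0")
  }
  if (!is.finite(cfg$o2_threshold_uM) || cfg$o2_threshold_uM <= 0) {
    stop_validation("o2_threshold_uM must be positive")
  }
  if (!is.logical(cfg$include_ambient_in_f15)) {
    stop_validation("include_ambient_in_f15 must be TRUE or FALSE")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror [default_config()]; values present
#' in the file override the defaults, and unknown keys are rejected with a
#' message listing the allowed ones.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  validate_config(modify_config(unclass(default_config()),
                                yaml::read_yaml(path)))
}

#' Isotope constants from a run configuration
#'
#' @param config A `run_config`.
#' @return The embedded [isotope_constants()].
#' @export
config_constants <- function(config) {
  isotope_constants(config$r_ref, config$r_air)
}

#' Tracer specification for a treatment under a configuration
#'
#' Builds the [compute_label_fraction()] tracer for a treatment, using the
#' configured addition and the ambient concentration of the matching
#' substrate.
#'
#' @param config A `run_config`.
#' @param treatment `"NO3"`, `"NO3_CAP"` or `"NH4"`.
#' @param ambient_umolL Ambient concentration of the treatment's substrate
#'   (\eqn{\mu}mol L\eqn{^{-1}}); default 0.
#' @return A `tracer_spec`.
#' @export
config_tracer <- function(config, treatment, ambient_umolL = 0) {
  if (!treatment %in% TREATMENTS) {
    stop_validation("unknown treatment '%s'", treatment)
  }
  t <- config$tracers[[treatment]]
  compute_label_fraction(
    substrate = treatment_substrate(treatment),
    added_nmol = t$added_nmol,
    purity_fraction = t$purity_fraction,
    ambient_umolL = ambient_umolL,
    liquid_volume_L = config$liquid_volume_L,
    constants = config_constants(config),
    include_ambient = config$include_ambient_in_f15
  )
}
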