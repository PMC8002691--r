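# Wire the stages together: fit every series, partition by depth, locate
# the interface, and integrate the fungal share.

#' Run the full analysis for one station
#'
#' Fits a production rate to every incubation series of one station,
#' partitions each depth that has both `NO3` and `NO3_CAP` fits into
#' fungal / bacterial / nitrification sources, locates the oxic-anoxic
#' interface in the station's O\eqn{_2} profile, and integrates the
#' fungal share from `z_top_m` (the oxycline) down to the interface.
#' Depths whose series cannot be fitted (e.g. fully censored) are not
#' silently dropped: they are listed in `excluded` with the reason.
#'
#' @param series List of [incubation_series()] for one station (e.g. from
#'   [read_incubations()]).
#' @param profile Profile data frame for the same station
#'   ([read_profile()] schema).
#' @param config A `run_config`.
#' @param z_top_m Top of the integration window (m). Required for the
#'   integration step; when `NULL`, integration is skipped.
#' @return List of class `station_analysis` with `rates` (data frame),
#'   `partition` (data frame or `NULL`), `interface_m`, `integration`
#'   (`integrated_contribution` or `NULL`) and `excluded` (data frame of
#'   skipped series with reasons).
#' @export
analyze_station <- function(series, profile, config = default_config(),
                            z_top_m = NULL) {
  stations <- unique(vapply(series, function(s) s$station, ""))
  if (length(stations) != 1L) {
    stop_validation("`series` must come from exactly one station, got: %s",
                    paste(stations, collapse = ", "))
  }
  prof <- profile[profile$station == stations, , drop = FALSE]
  if (nrow(prof) < 2L) {
    stop_validation("profile has < 2 depths for station %s", stations)
  }
  constants <- config_constants(config)

  fits <- list()
  excluded <- list()
  for (s in series) {
    res <- tryCatch(
      fit_rate(s, constants,
               detection_limit_nmolN = config$detection_limit_nmolN),
      tracern2o_error = function(e) e)
    if (inherits(res, "rate_estimate")) {
      fits[[length(fits) + 1L]] <- res
    } else {
      excluded[[length(excluded) + 1L]] <- data.frame(
        station = s$station, depth_m = s$depth_m, treatment = s$treatment,
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    }
  }
  if (length(fits) == 0L) {
    stop_estimation("no series could be fitted for station %s", stations)
  }
  rates <- rates_table(fits)
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(station = character(), depth_m = numeric(),
               treatment = character(), reason = character(),
               stringsAsFactors = FALSE)

  by_depth <- split(fits, vapply(fits, function(f) f$depth_m, 0))
  parts <- list()
  for (grp in by_depth) {
    trs <- vapply(grp, function(f) f$treatment, "")
    if (!all(c("NO3", "NO3_CAP") %in% trs)) next
    depth <- grp[[1]]$depth_m
    o2 <- if (depth %in% prof$depth_m) {
      prof$o2_uM[prof$depth_m == depth][1]
    } else NA_real_
    parts[[length(parts) + 1L]] <- partition_depth(
      total = grp[[which(trs == "NO3")[1]]],
      cap = grp[[which(trs == "NO3_CAP")[1]]],
      nh4 = if ("NH4" %in% trs) grp[[which(trs == "NH4")[1]]] else NULL,
      o2_uM = o2)
  }
  partition <- if (length(parts)) partition_table(parts) else NULL

  interface <- tryCatch(
    find_interface(prof$depth_m, prof$o2_uM, config$o2_threshold_uM),
    tracern2o_error = function(e) NA_real_)

  integration <- NULL
  if (!is.null(z_top_m) && !is.null(partition) && is.finite(interface)) {
    integration <- integrate_contribution(partition, z_top_m, interface)
  }
  structure(list(station = stations, rates = rates, partition = partition,
                 interface_m = interface, integration = integration,
                 excluded = excluded),
            class = "station_analysis")
}

#' @export
print.station_analysis <- function(x, ...) {
  cat("Station", x$station, "analysis:", nrow(x$rates), "rate estimates\n")
  if (!is.null(x$integration)) print(x$integration)
  invisible(x)
}

#' Render a run report
#'
#' Produces a human-readable markdown report for one or more station
#' analyses: the per-depth rate table, the source partition with clamp and
#' floor flags, the integration summary, and any series excluded from
#' fitting with the reason.
#'
#' @param analyses A `station_analysis` or list of them.
#' @param path Optional file to write the report to.
#' @return Character vector of markdown lines, invisibly if `path` is
#'   given.
#' @export
report <- function(analyses, path = NULL) {
  if (inherits(analyses, "station_analysis")) analyses <- list(analyses)
  if (length(analyses) == 0L) {
    stop_validation("no analyses to report")
  }
  fmt_table <- function(df) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 6) else as.character(col)
    }, FUN.VALUE = character(nrow(df)))
    cells <- matrix(cells, nrow = nrow(df),
                    dimnames = list(NULL, names(df)))
    c(paste0("| ", paste(colnames(cells), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(cells)), collapse = "|"), "|"),
      apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  }
  lines <- c("# N2O production rate report", "")
  for (a in analyses) {
    lines <- c(lines, sprintf("## Station %s", a$station), "",
               "### Rates (nmol N/L/d)", "", fmt_table(a$rates), "")
    if (!is.null(a$partition)) {
      lines <- c(lines, "### Source partition", "", fmt_table(a$partition), "")
    }
    if (is.finite(a$interface_m)) {
      lines <- c(lines, sprintf("Oxic-anoxic interface: %.2f m",
                                a$interface_m), "")
    }
    if (!is.null(a$integration)) {
      i <- a$integration
      lines <- c(lines, "### Integration", "", sprintf(
        "Fungal contribution %.4g-%.4g m: %.4g of %.4g umol N/m2/d = **%.3g%%**",
        i$z_top_m, i$z_bottom_m, i$integral_fungal, i$integral_total_no3,
        i$fungal_fraction_percent), "")
    }
    if (nrow(a$excluded) > 0L) {
      lines <- c(lines, "### Excluded series", "", fmt_table(a$excluded), "")
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
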