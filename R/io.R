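# CSV readers/writers for the pipeline's tabular schemas. Numbers are
# written with 17 significant digits so write-then-read round-trips
# doubles exactly.

write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- sprintf("%.17g", out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table <- function(path, required_cols) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop_validation("%s: missing column(s): %s", path,
                    paste(missing, collapse = ", "))
  }
  df
}

#' Read a hydrographic depth profile
#'
#' Expects columns `station, depth_m, o2_uM, no3_umolL, nh4_umolL`.
#' Depths must be strictly increasing within each station.
#'
#' @param path Path to `profile.csv`.
#' @return Data frame sorted by station then depth.
#' @export
read_profile <- function(path) {
  df <- read_table(path, c("station", "depth_m", "o2_uM", "no3_umolL",
                           "nh4_umolL"))
  if (any(!is.finite(df$depth_m)) || any(!is.finite(df$o2_uM)) ||
      any(df$o2_uM < 0)) {
    stop_validation("%s: depth_m must be finite and o2_uM finite and >= 0",
                    path)
  }
  df <- df[order(df$station, df$depth_m), ]
  for (st in unique(df$station)) {
    d <- df$depth_m[df$station == st]
    if (any(duplicated(d))) {
      stop_validation("%s: duplicate depths at station %s", path, st)
    }
  }
  rownames(df) <- NULL
  df
}

#' Read incubation time series from CSV
#'
#' Expects columns `station, depth_m, treatment, time_h, n2o_nmolN,
#' delta15n_permil`, with treatments in `NO3 | NO3_CAP | NH4`. Rows are
#' grouped into one [incubation_series()] per (station, depth, treatment),
#' ordered by station, depth, then time; the tracer for each series is
#' built from the run configuration, taking the ambient substrate
#' concentration from the matching profile row when a profile is given.
#'
#' @param path Path to `incubations.csv`.
#' @param config A `run_config`.
#' @param profile Optional profile data frame from [read_profile()]; when
#'   absent, ambient concentrations are taken as zero.
#' @return List of `incubation_series`.
#' @export
read_incubations <- function(path, config = default_config(),
                             profile = NULL) {
  df <- read_table(path, c("station", "depth_m", "treatment", "time_h",
                           "n2o_nmolN", "delta15n_permil"))
  bad <- which(!df$treatment %in% TREATMENTS)
  if (length(bad) > 0L) {
    stop_validation(
      "%s: invalid treatment '%s' at row %d; allowed values: %s", path,
      df$treatment[bad[1]], bad[1], paste(TREATMENTS, collapse = ", "))
  }
  bad <- which(!is.finite(df$n2o_nmolN) | df$n2o_nmolN < 0)
  if (length(bad) > 0L) {
    stop_validation("%s: n2o_nmolN must be finite and >= 0 (first bad row: %d)",
                    path, bad[1])
  }
  bad <- which(!is.finite(df$time_h) | df$time_h < 0)
  if (length(bad) > 0L) {
    stop_validation("%s: time_h must be finite and >= 0 (first bad row: %d)",
                    path, bad[1])
  }
  key <- paste(df$station, df$depth_m, df$treatment, df$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop_validation(
      "%s: duplicate (station, depth, treatment, time) rows: %s", path,
      paste(utils::head(dups, 10L), collapse = ", "))
  }
  series_from_table(df, config, profile)
}

#' Group an incubation table into series
#'
#' In-memory counterpart of [read_incubations()]: takes a data frame in
#' the `incubations.csv` schema (e.g. straight from
#' [generate_station()]`$incubations`) and groups it into
#' [incubation_series()] objects with tracers built from the
#' configuration.
#'
#' @param df Data frame with columns `station, depth_m, treatment,
#'   time_h, n2o_nmolN, delta15n_permil`.
#' @inheritParams read_incubations
#' @return List of `incubation_series`.
#' @export
series_from_table <- function(df, config = default_config(),
                              profile = NULL) {
  groups <- split(df, paste(df$station, df$depth_m, df$treatment, sep = "\r"))
  series <- lapply(groups, function(g) {
    ambient <- 0
    if (!is.null(profile)) {
      hit <- profile$station == g$station[1] & profile$depth_m == g$depth_m[1]
      if (any(hit)) {
        ambient <- switch(treatment_substrate(g$treatment[1]),
                          nitrate = profile$no3_umolL[hit][1],
                          ammonium = profile$nh4_umolL[hit][1])
      }
    }
    incubation_series(
      station = g$station[1], depth_m = g$depth_m[1],
      treatment = g$treatment[1],
      tracer = config_tracer(config, g$treatment[1], ambient_umolL = ambient),
      measurements = g[, c("time_h", "n2o_nmolN", "delta15n_permil")])
  })
  ord <- order(vapply(series, function(s) s$station, ""),
               vapply(series, function(s) s$depth_m, 0),
               match(vapply(series, function(s) s$treatment, ""), TREATMENTS))
  unname(series[ord])
}

#' Write the pipeline's output tables
#'
#' `write_rates()`, `write_partition()` and `write_integration()` write
#' the per-series rate table, the per-depth partition table and the
#' integration summary as CSV with full floating-point precision, so
#' reading them back reproduces the in-memory values exactly.
#'
#' @param df The corresponding data frame ([rates_table()],
#'   [partition_table()], or `as.data.frame()` of an
#'   `integrated_contribution`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rates <- function(df, path) write_table(df, path)

#' @rdname write_rates
#' @export
write_partition <- function(df, path) write_table(df, path)

#' @rdname write_rates
#' @export
write_integration <- function(df, path) write_table(df, path)
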