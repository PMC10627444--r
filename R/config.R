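#' Framework configuration
#'
#' Bundles every tunable constant of the assessment framework.  The defaults
#' reproduce the published application: 150 m land-cover buffer, 4-connected
#' edge/flood connectivity, six inundation scenarios at 1..6 ft (0.3048 ..
#' 1.8288 m) above MHHW, connectedness evaluated at 1.2 m of sea level rise,
#' hardened-shoreline weight 1.5, migration-space weight 2, and ordinal
#' thresholds 6 / -6.
#'
#' @param buffer_m land-cover buffer around each unit, meters.
#' @param connectivity 4 or 8, for edge detection and flood fills.
#' @param scenarios_m inundation depths above MHHW, meters.
#' @param connectedness_slr_m SLR scenario for connectedness, meters.
#' @param migration_connected require hydrologic connectivity for migration
#'   space (`FALSE` reproduces an unconnected "bathtub" fill).
#' @param thresholds ordinal cuts: `high` for condition/adaptive,
#'   `vuln_high` for vulnerability.
#' @param dirs a [metric_directions()] (signs and weights).
#' @param sd_denominator `"n-1"` or `"n"` for summary SDs.
#' @param seed integer seed driving all synthetic-data randomness.
#' @return A `framework_config` list.
#' @export
framework_config <- function(buffer_m = 150,
                             connectivity = 4,
                             scenarios_m = (1:6) * 0.3048,
                             connectedness_slr_m = 1.2,
                             migration_connected = TRUE,
                             thresholds = list(high = 6, vuln_high = -6),
                             dirs = metric_directions(),
                             sd_denominator = "n-1",
                             seed = 1L) {
  stopifnot(buffer_m >= 0, connectivity %in% c(4, 8))
  structure(list(buffer_m = buffer_m, connectivity = connectivity,
                 scenarios_m = as.numeric(scenarios_m),
                 connectedness_slr_m = connectedness_slr_m,
                 migration_connected = isTRUE(migration_connected),
                 thresholds = thresholds, dirs = dirs,
                 sd_denominator = sd_denominator, seed = as.integer(seed)),
            class = "framework_config")
}

#' Read / write a framework configuration as JSON
#'
#' @param path file path.
#' @param config a [framework_config()].
#' @return `read_config()` returns a `framework_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dirs <- metric_directions(
    sign = if (!is.null(raw$sign)) unlist(raw$sign),
    weight = if (!is.null(raw$weight)) unlist(raw$weight))
  defaults <- framework_config()
  framework_config(
    buffer_m = raw$buffer_m %||% defaults$buffer_m,
    connectivity = raw$connectivity %||% defaults$connectivity,
    scenarios_m = raw$scenarios_m %||% defaults$scenarios_m,
    connectedness_slr_m = raw$connectedness_slr_m %||% defaults$connectedness_slr_m,
    migration_connected = raw$migration_connected %||% defaults$migration_connected,
    thresholds = utils::modifyList(defaults$thresholds,
                                   as.list(raw$thresholds %||% list())),
    dirs = dirs,
    sd_denominator = raw$sd_denominator %||% defaults$sd_denominator,
    seed = raw$seed %||% defaults$seed)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  out <- list(buffer_m = config$buffer_m, connectivity = config$connectivity,
              scenarios_m = config$scenarios_m,
              connectedness_slr_m = config$connectedness_slr_m,
              migration_connected = config$migration_connected,
              thresholds = config$thresholds,
              sign = as.list(config$dirs$sign),
              weight = as.list(config$dirs$weight),
              sd_denominator = config$sd_denominator,
              seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
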