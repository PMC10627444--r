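# Readers/writers: ESRI ASCII grids for rasters, GeoJSON for vectors, CSV
# for tables, JSON for configuration and run manifests.  Everything is
# plain text and round-trips without value drift beyond 1e-7.

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` interchange: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows north to south.
#'
#' @param grid a [raster_grid()].
#' @param path file path (`.asc`).
#' @param digits significant digits written for numeric grids.
#' @return `read_ascii_grid()` returns a [raster_grid()] (`crs_id` is not
#'   stored in the format and must be supplied).
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  nodata <- -9999
  yll <- grid$origin[2] - nr * grid$cell_size
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %d", nodata))
  out <- v
  out[is.na(out)] <- nodata
  body <- apply(out, 1, function(r) paste(formatC(r, digits = digits,
                                                  format = "g"),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs_id CRS identifier to attach on read.
#' @param integer_values coerce cell values to integer (for class-code grids).
#' @export
read_ascii_grid <- function(path, crs_id = "local-planar-m",
                            integer_values = FALSE) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), tolower(vapply(hdr, `[`, "", 1)))
  nc <- as.integer(kv[["ncols"]]); nr <- as.integer(kv[["nrows"]])
  cs <- as.numeric(kv[["cellsize"]])
  xll <- as.numeric(kv[["xllcorner"]]); yll <- as.numeric(kv[["yllcorner"]])
  nodata <- as.numeric(kv[["nodata_value"]])
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  if (integer_values) storage.mode(m) <- "integer"
  raster_grid(m, cell_size = cs, origin = c(xll, yll + nr * cs),
              crs_id = crs_id)
}

# ---- GeoJSON vectors --------------------------------------------------------

coords_list <- function(mat) lapply(seq_len(nrow(mat)),
                                    function(i) c(mat[i, 1], mat[i, 2]))

#' Write / read marsh units as GeoJSON
#'
#' Polygons with `unit_id` and the grouping labels as feature properties.
#'
#' @param units list of [marsh_unit()].
#' @param path file path (`.geojson`).
#' @return `read_units_geojson()` returns a list of [marsh_unit()].
#' @export
write_units_geojson <- function(units, path) {
  feats <- lapply(units, function(u) {
    list(type = "Feature",
         properties = c(list(unit_id = u$unit_id), u$groups),
         geometry = list(type = "Polygon",
                         coordinates = list(coords_list(u$boundary))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_units_geojson
#' @export
read_units_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    props <- f$properties
    marsh_unit(unit_id = props$unit_id, boundary = ring,
               groups = props[setdiff(names(props), "unit_id")])
  })
}

#' Write / read shoreline segments as GeoJSON
#'
#' LineStrings with `hardened` and `unit_id` feature properties.
#'
#' @param segments list of [shoreline_segment()].
#' @param path file path (`.geojson`).
#' @return `read_shorelines_geojson()` returns a list of
#'   [shoreline_segment()].
#' @export
write_shorelines_geojson <- function(segments, path) {
  feats <- lapply(segments, function(s) {
    list(type = "Feature",
         properties = list(unit_id = s$unit_id, hardened = s$hardened),
         geometry = list(type = "LineString",
                         coordinates = coords_list(s$vertices)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shorelines_geojson
#' @export
read_shorelines_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(gj$features, function(f) {
    verts <- do.call(rbind, lapply(f$geometry$coordinates,
                                   function(p) c(p[[1]], p[[2]])))
    shoreline_segment(verts, hardened = isTRUE(f$properties$hardened),
                      unit_id = f$properties$unit_id)
  })
}

# ---- class tables and metric tables ----------------------------------------

#' Write / read a class table as CSV
#' @param ct a [class_table()].
#' @param path file path.
#' @return `read_class_table()` returns a [class_table()].
#' @export
write_class_table <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_class_table
#' @export
read_class_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class_table(d$code, d$label, d$is_marsh, d$is_vegetated, d$is_water,
              d$is_natural, d$is_agricultural, d$is_migratable,
              d$impervious_fraction)
}

#' Read / write metric and score tables as CSV
#'
#' CSV is the canonical tabular interchange (UTF-8, `.` decimal, `unit_id`
#' key).  `read_metric_table()` validates the 13 metric columns and their
#' range invariants.
#'
#' @param path file path.
#' @param table a data.frame.
#' @return `read_metric_table()` returns a validated data.frame.
#' @export
read_metric_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  mc <- metric_columns()
  missing_cols <- setdiff(c("unit_id", mc$all), names(d))
  if (length(missing_cols)) {
    stop("metric CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(d$unit_id)) stop("duplicate unit_id in metric CSV")
  for (m in grep("^pct_", mc$all, value = TRUE)) {
    v <- d[[m]]
    if (any(is.finite(v) & (v < 0 | v > 100))) {
      stop("percent column out of [0, 100]: ", m)
    }
  }
  for (m in c("area_to_edge_ratio", "unveg_edge_ratio", "soil_erodibility",
              "tidal_range_m", "migration_ratio")) {
    if (any(is.finite(d[[m]]) & d[[m]] < 0)) stop("negative values in ", m)
  }
  d
}

#' @rdname read_metric_table
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- landscapes -------------------------------------------------------------

#' Write / read a full landscape directory
#'
#' Serializes a [landscape()] to a directory of plain-text files:
#' `landcover.asc`, `elevation.asc`, `erodibility.asc`, gridded datums as
#' `mhhw.asc`/`mtl.asc`/`mllw.asc` (constants go to `meta.json`),
#' `class_table.csv`, `units.geojson`, `shorelines.geojson`, `meta.json`
#' (CRS id, datum constants).
#'
#' @param ls a [landscape()].
#' @param dir output directory (created if absent).
#' @return `read_landscape()` returns a validated [landscape()]; alignment
#'   or unknown-code problems are hard errors.
#' @export
write_landscape <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(ls$landcover, file.path(dir, "landcover.asc"))
  write_ascii_grid(ls$elevation, file.path(dir, "elevation.asc"))
  write_ascii_grid(ls$erodibility, file.path(dir, "erodibility.asc"))
  meta <- list(crs_id = ls$landcover$crs_id, tides = list())
  for (f in c("mhhw", "mtl", "mllw")) {
    v <- ls$tides[[f]]
    if (is.matrix(v)) {
      write_ascii_grid(raster_grid(v, ls$landcover$cell_size,
                                   ls$landcover$origin, ls$landcover$crs_id),
                       file.path(dir, paste0(f, ".asc")))
      meta$tides[[f]] <- "grid"
    } else meta$tides[[f]] <- v
  }
  write_class_table(ls$class_table, file.path(dir, "class_table.csv"))
  write_units_geojson(ls$units, file.path(dir, "units.geojson"))
  write_shorelines_geojson(ls$shorelines, file.path(dir, "shorelines.geojson"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  crs <- meta$crs_id
  ct <- read_class_table(file.path(dir, "class_table.csv"))
  lc_raw <- read_ascii_grid(file.path(dir, "landcover.asc"), crs,
                            integer_values = TRUE)
  lc <- land_cover_grid(lc_raw$values, ct, lc_raw$cell_size, lc_raw$origin, crs)
  elev <- read_ascii_grid(file.path(dir, "elevation.asc"), crs)
  erod <- read_ascii_grid(file.path(dir, "erodibility.asc"), crs)
  td <- lapply(c(mhhw = "mhhw", mtl = "mtl", mllw = "mllw"), function(f) {
    spec <- meta$tides[[f]]
    if (identical(spec, "grid")) {
      read_ascii_grid(file.path(dir, paste0(f, ".asc")), crs)$values
    } else as.numeric(spec)
  })
  tides <- tidal_surface(td$mhhw, td$mtl, td$mllw)
  units <- read_units_geojson(file.path(dir, "units.geojson"))
  shor <- read_shorelines_geojson(file.path(dir, "shorelines.geojson"))
  landscape(lc, elev, tides, erod, shor, units, ct)
}
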