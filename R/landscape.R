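#' Canonical metric column names
#'
#' The thirteen resilience metrics, grouped into the three categories used
#' throughout scoring.  Column names are the package-wide contract for metric
#' tables.
#'
#' @return Named list with character vectors `condition`, `vulnerability`,
#'   `adaptive`, and `all`.
#' @export
metric_columns <- function() {
  condition <- c("area_to_edge_ratio", "unveg_edge_ratio", "pct_impervious",
                 "pct_natural", "pct_agricultural")
  vulnerability <- c("soil_erodibility", "tidal_range_m", "pct_below_mhhw",
                     "pct_below_mtl")
  adaptive <- c("pct_hardened", "shoreline_complexity", "migration_ratio",
                "connectedness")
  list(condition = condition, vulnerability = vulnerability,
       adaptive = adaptive, all = c(condition, vulnerability, adaptive))
}

#' Assemble a landscape
#'
#' Bundles the aligned rasters, tidal datums, shoreline segments, marsh units
#' and the class table into one validated object consumed by the metric
#' engines.
#'
#' @param landcover a [land_cover_grid()].
#' @param elevation a [raster_grid()] of elevation in meters, aligned with
#'   `landcover`.
#' @param tides a [tidal_surface()].
#' @param erodibility a [raster_grid()] of soil-erodibility K factors,
#'   aligned with `landcover`.
#' @param shorelines list of [shoreline_segment()].
#' @param units list of [marsh_unit()].
#' @param class_tab a [class_table()]; defaults to the land-cover grid's.
#' @return A `landscape` object.
#' @export
landscape <- function(landcover, elevation, tides, erodibility,
                      shorelines = list(), units,
                      class_tab = landcover$class_table) {
  stopifnot_aligned(landcover, elevation, "landcover and elevation")
  stopifnot_aligned(landcover, erodibility, "landcover and erodibility")
  for (f in c("mhhw", "mtl", "mllw")) {
    v <- tides[[f]]
    if (is.matrix(v) && !identical(dim(v), dim(landcover$values))) {
      stop("tidal surface '", f, "' is not aligned with the land-cover grid")
    }
  }
  ids <- vapply(units, function(u) u$unit_id, "")
  if (anyDuplicated(ids)) stop("duplicate unit ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seg_ids <- vapply(shorelines, function(s) s$unit_id, "")
  orphan <- setdiff(seg_ids, ids)
  if (length(orphan)) stop("shoreline segments reference unknown units: ",
                           paste(unique(orphan), collapse = ", "))
  ke <- erodibility$values
  if (any(is.finite(ke) & ke < 0)) stop("erodibility K factors must be >= 0")
  structure(list(landcover = landcover, elevation = elevation, tides = tides,
                 erodibility = erodibility, shorelines = shorelines,
                 units = units, class_table = class_tab),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape: %d x %d cells @ %.6g m, %d units, %d shoreline segments>\n",
              nrow(x$landcover$values), ncol(x$landcover$values),
              x$landcover$cell_size, length(x$units), length(x$shorelines)))
  invisible(x)
}

# per-unit logical masks (cell-center in polygon), named by unit id
landscape_unit_masks <- function(ls) {
  masks <- lapply(ls$units, unit_mask, grid = ls$landcover)
  names(masks) <- vapply(ls$units, function(u) u$unit_id, "")
  masks
}

# grouping labels as a data.frame joined on unit_id
landscape_groups <- function(ls) {
  ids <- vapply(ls$units, function(u) u$unit_id, "")
  labs <- unique(unlist(lapply(ls$units, function(u) names(u$groups))))
  out <- data.frame(unit_id = ids, stringsAsFactors = FALSE)
  for (lb in labs) {
    out[[lb]] <- vapply(ls$units, function(u) {
      v <- u$groups[[lb]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, "")
  }
  out
}
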