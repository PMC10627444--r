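# Vulnerability metrics: soil erodibility, tidal range, and marsh elevation
# relative to tidal datums.

#' Mean soil erodibility over a unit
#'
#' Arithmetic mean of the K factor over non-nodata cells in the unit mask.
#'
#' @param erodibility a [raster_grid()] of K factors.
#' @param mask logical matrix selecting the unit's cells.
#' @return unitless K >= 0, or `NA` when every cell is nodata.
#' @export
mean_erodibility <- function(erodibility, mask) {
  v <- erodibility$values[mask]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Mean tidal range over a unit
#'
#' Height difference MHHW - MLLW in meters, averaged over the unit when the
#' datums are gridded.
#'
#' @param tides a [tidal_surface()].
#' @param mask logical matrix selecting the unit's cells.
#' @return meters >= 0, or `NA` when undefined.
#' @export
tidal_range <- function(tides, mask) {
  idx <- which(mask)
  hi <- datum_at(tides, "mhhw", idx)
  lo <- datum_at(tides, "mllw", idx)
  ok <- !is.na(hi) & !is.na(lo)
  if (!any(ok)) return(NA_real_)
  mean(hi[ok] - lo[ok])
}

#' Percent of marsh below a tidal datum
#'
#' Share of marsh cells whose elevation is strictly below MHHW or MTL
#' (evaluated per cell when the datums are gridded).  Cells exactly at the
#' datum count as not-below.
#'
#' @param level `"mhhw"` or `"mtl"`.
#' @param elevation a [raster_grid()] of elevations (meters).
#' @param tides a [tidal_surface()].
#' @param marsh_mask logical matrix, `TRUE` on the unit's marsh cells.
#' @return percent in \[0, 100\], or `NA` for an empty marsh mask.
#' @export
pct_marsh_below <- function(level = c("mhhw", "mtl"), elevation, tides,
                            marsh_mask) {
  level <- match.arg(level)
  idx <- which(marsh_mask)
  if (!length(idx)) return(NA_real_)
  e <- elevation$values[idx]
  d <- datum_at(tides, level, idx)
  ok <- !is.na(e) & !is.na(d)
  if (!any(ok)) return(NA_real_)
  100 * sum(e[ok] < d[ok]) / sum(ok)
}
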