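#' Planar raster grids
#'
#' All rasters in the package share one lightweight representation: a numeric
#' or integer matrix plus planar geometry metadata.  Coordinates are planar
#' meters in a projected CRS that is recorded but never transformed.  Row 1 is
#' the north edge; the center of cell \[row, col\] is at
#' `origin + (col - 0.5, -(row - 0.5)) * cell_size`.  Areas are cell counts
#' times `cell_size^2`.  Nodata cells are stored as `NA`.
#'
#' @param values matrix of cell values (`NA` = nodata).
#' @param cell_size cell edge length in meters (> 0).
#' @param origin numeric length-2, planar (x, y) of the grid's upper-left
#'   corner in meters.
#' @param crs_id text identifier of the projected CRS (recorded only).
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, cell_size, origin = c(0, 0),
                        crs_id = "local-planar-m") {
  if (!is.matrix(values) || length(values) == 0) {
    stop("values must be a non-empty matrix")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("cell_size must be a single positive number (meters)")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_id = as.character(crs_id)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid %d x %d, cell %.6g m, origin (%.6g, %.6g), crs %s>\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$crs_id))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Planar coordinates of every cell center
#'
#' @param grid a `raster_grid`.
#' @return list with matrices `x` and `y` of cell-center coordinates (meters).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  x <- grid$origin[1] + (matrix(rep(seq_len(nc), each = nr), nr) - 0.5) * cs
  y <- grid$origin[2] - (matrix(rep(seq_len(nr), times = nc), nr) - 0.5) * cs
  list(x = x, y = y)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

stopifnot_aligned <- function(a, b, what = "grids") {
  if (!same_geometry(a, b)) {
    stop(what, " are not aligned: shapes ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"),
         ", cell sizes ", a$cell_size, " vs ", b$cell_size)
  }
  invisible(TRUE)
}

#' Land-cover grid
#'
#' A `raster_grid` of integer class codes validated against a [class_table()].
#'
#' @param codes integer matrix of class codes (`NA` = nodata).
#' @param class_tab a [class_table()]; every non-nodata code must appear in it.
#' @inheritParams raster_grid
#' @return A `land_cover_grid` (subclass of `raster_grid`).
#' @export
land_cover_grid <- function(codes, class_tab, cell_size, origin = c(0, 0),
                            crs_id = "local-planar-m") {
  storage.mode(codes) <- "integer"
  g <- raster_grid(codes, cell_size, origin, crs_id)
  used <- unique(codes[!is.na(codes)])
  unknown <- setdiff(used, class_tab$code)
  if (length(unknown)) {
    stop("land-cover codes absent from the class table: ",
         paste(sort(unknown), collapse = ", "))
  }
  g$class_table <- class_tab
  class(g) <- c("land_cover_grid", class(g))
  g
}

#' Tidal datum surface
#'
#' Holds the three tidal datums (MHHW, MTL, MLLW) in the elevation grid's
#' vertical datum, either as single constants applied everywhere or as grids
#' aligned with the elevation raster.  The ordering MLLW <= MTL <= MHHW is
#' enforced wherever all three are defined.
#'
#' @param mhhw,mtl,mllw single numbers (meters) or matrices aligned with the
#'   elevation grid.
#' @return A `tidal_surface` object.
#' @export
tidal_surface <- function(mhhw, mtl, mllw) {
  as_field <- function(v) if (is.matrix(v)) v else as.numeric(v)[1]
  ts <- structure(list(mhhw = as_field(mhhw), mtl = as_field(mtl),
                       mllw = as_field(mllw)),
                  class = "tidal_surface")
  chk <- function(lo, hi, lab) {
    both <- !is.na(lo) & !is.na(hi)
    if (any(lo[both] > hi[both] + 1e-12)) stop("tidal datum ordering violated: ", lab)
  }
  # broadcast constants against matrices for the check
  m <- function(v) if (is.matrix(v)) v else matrix(v)
  chk(m(ts$mllw), m(ts$mtl), "MLLW > MTL")
  chk(m(ts$mtl), m(ts$mhhw), "MTL > MHHW")
  ts
}

# evaluate a datum over a cell index set; returns a vector, one per cell
datum_at <- function(ts, which, idx, ref_dim) {
  v <- ts[[which]]
  if (is.matrix(v)) v[idx] else rep(v, length(idx))
}
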