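#' Marsh unit polygon
#'
#' The marsh unit is the atom of all scoring: a planar polygon with a unique
#' identifier (the "MUC") and optional grouping labels (region, state,
#' reserve, ...) used by [group_summary()].
#'
#' @param unit_id text identifier, unique within an analysis.
#' @param boundary two-column matrix of (x, y) vertices in meters; a single
#'   outer ring, closed or open (the closing vertex is added if absent).
#' @param groups named character vector or list of grouping labels.
#' @return A `marsh_unit` object.
#' @export
marsh_unit <- function(unit_id, boundary, groups = list()) {
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 3) {
    stop("boundary must be an (n >= 3) x 2 matrix of planar vertices")
  }
  # close the ring
  if (any(boundary[1, ] != boundary[nrow(boundary), ])) {
    boundary <- rbind(boundary, boundary[1, ])
  }
  if (abs(ring_area(boundary)) <= 0) stop("degenerate unit polygon: ", unit_id)
  structure(list(unit_id = as.character(unit_id), boundary = boundary,
                 groups = as.list(groups)),
            class = "marsh_unit")
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorized ray casting over a single closed ring.  Points exactly on an
#' edge may fall on either side; cell-center tests never sit on unit
#' boundaries in generated landscapes, and users are expected to avoid
#' degenerate cell-center/vertex coincidence.
#'
#' @param px,py point coordinates (vectors).
#' @param ring closed two-column vertex matrix.
#' @return logical vector.
#' @keywords internal
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1
  inside <- logical(length(px))
  x <- ring[, 1]; y <- ring[, 2]
  for (i in seq_len(n)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1]; y2 <- y[i + 1]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- crosses
      hit[crosses] <- px[crosses] < xint
      inside <- xor(inside, hit)
    }
  }
  inside
}

# minimum distance from points to a polyline/ring (vectorized over points)
points_segment_dist <- function(px, py, verts) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(verts) - 1)) {
    ax <- verts[i, 1]; ay <- verts[i, 2]
    bx <- verts[i + 1, 1]; by <- verts[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dd <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      dd <- (px - ax - t * vx)^2 + (py - ay - t * vy)^2
    }
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

#' Rasterize a marsh unit to a cell mask
#'
#' Membership by cell-center test, optionally dilated by a Euclidean buffer:
#' a cell belongs to the buffered unit iff its center lies inside the polygon
#' or within `buffer_m` of the polygon boundary.
#'
#' @param unit a [marsh_unit()].
#' @param grid a [raster_grid()] providing the geometry.
#' @param buffer_m buffer distance in meters (default 0).
#' @return logical matrix, `TRUE` where the cell center is in the (buffered)
#'   unit.
#' @export
unit_mask <- function(unit, grid, buffer_m = 0) {
  cc <- cell_centers(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  mask <- matrix(FALSE, nr, nc)
  bb <- apply(unit$boundary, 2, range)
  cand <- which(cc$x >= bb[1, 1] - buffer_m & cc$x <= bb[2, 1] + buffer_m &
                cc$y >= bb[1, 2] - buffer_m & cc$y <= bb[2, 2] + buffer_m)
  if (!length(cand)) return(mask)
  px <- cc$x[cand]; py <- cc$y[cand]
  inside <- points_in_ring(px, py, unit$boundary)
  if (buffer_m > 0) {
    near <- points_segment_dist(px, py, unit$boundary) <= buffer_m
    inside <- inside | near
  }
  mask[cand] <- inside
  mask
}

#' Shoreline segment
#'
#' An attributed polyline: ordered planar vertices, a hardened/natural flag,
#' and the id of the marsh unit it belongs to.
#'
#' @param vertices (n >= 2) x 2 matrix of planar coordinates in meters.
#' @param hardened logical: `TRUE` for armored/hardened shoreline.
#' @param unit_id id of the owning marsh unit.
#' @return A `shoreline_segment` object.
#' @export
shoreline_segment <- function(vertices, hardened, unit_id) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 2) {
    stop("a shoreline segment needs >= 2 planar vertices")
  }
  if (polyline_length(vertices) <= 0) stop("zero-length shoreline segment")
  structure(list(vertices = vertices, hardened = isTRUE(hardened),
                 unit_id = as.character(unit_id)),
            class = "shoreline_segment")
}

#' @rdname shoreline_segment
#' @param vertices vertex matrix of an open polyline.
#' @return `polyline_length()`: total path length in meters.
#' @export
polyline_length <- function(vertices) {
  d <- diff(vertices)
  sum(sqrt(rowSums(d^2)))
}
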