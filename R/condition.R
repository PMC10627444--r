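# Current-condition metrics: marsh configuration (core/edge) and buffered
# land-cover fractions.

# logical neighbour shift helpers: pad with NA so border cells see nodata
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else stop("connectivity must be 4 or 8")
}

#' Classify marsh cells as core or edge
#'
#' A marsh cell is an edge cell iff at least one neighbour (4-connected by
#' default) is non-nodata and not marsh; edge cells whose offending
#' neighbour is unvegetated (open water, flat, bare, developed) are
#' unvegetated edge, otherwise vegetated edge.  All remaining marsh cells
#' are core.  Nodata neighbours are ignored; cells outside the grid do not
#' make a cell edge.
#'
#' @param landcover a [land_cover_grid()].
#' @param class_tab a [class_table()] (defaults to the grid's own).
#' @param mask logical matrix selecting the unit's cells (`NULL` = whole
#'   grid).
#' @param connectivity 4 (rook, default) or 8 (queen).
#' @return A `core_edge_labels` list: `labels` (character matrix with
#'   `"core"`, `"edge"`, `"non_marsh"` or `NA` outside the mask), `n_core`,
#'   `n_edge`, `n_unveg_edge`, `n_veg_edge`.
#' @export
classify_core_edge <- function(landcover, class_tab = landcover$class_table,
                               mask = NULL, connectivity = 4) {
  codes <- landcover$values
  if (is.null(mask)) mask <- matrix(TRUE, nrow(codes), ncol(codes))
  if (!any(mask)) stop("empty unit mask")
  marsh <- codes_to_flag(codes, class_tab, "is_marsh")
  veg <- codes_to_flag(codes, class_tab, "is_vegetated")
  marsh[is.na(marsh)] <- FALSE

  # neighbour is "exposed" if non-nodata and not marsh; "unvegetated
  # exposure" additionally requires the neighbour not vegetated
  exposed <- !is.na(codes) & !marsh
  unveg_exp <- exposed & (is.na(veg) | !veg)

  any_exposed <- matrix(FALSE, nrow(codes), ncol(codes))
  any_unveg <- matrix(FALSE, nrow(codes), ncol(codes))
  for (off in neighbor_offsets(connectivity)) {
    any_exposed <- any_exposed | shift_mat(exposed, off[1], off[2], FALSE)
    any_unveg <- any_unveg | shift_mat(unveg_exp, off[1], off[2], FALSE)
  }

  m <- marsh & mask
  lab <- matrix(NA_character_, nrow(codes), ncol(codes))
  lab[mask & !m] <- "non_marsh"
  lab[m & any_exposed] <- "edge"
  lab[m & !any_exposed] <- "core"
  unveg_edge <- m & any_exposed & any_unveg
  structure(list(labels = lab,
                 n_core = sum(m & !any_exposed),
                 n_edge = sum(m & any_exposed),
                 n_unveg_edge = sum(unveg_edge),
                 n_veg_edge = sum(m & any_exposed & !any_unveg)),
            class = "core_edge_labels")
}

#' Core-to-edge area ratio
#'
#' Ratio of core marsh cells to edge marsh cells; more core per unit of edge
#' means less exposure to erosive wave action.  When a unit has marsh but no
#' edge cells the denominator is taken as 1 (documented convention); a unit
#' with no marsh cells yields `NA`.
#'
#' @param labels a `core_edge_labels` from [classify_core_edge()].
#' @return unitless ratio >= 0, or `NA`.
#' @export
area_to_edge_ratio <- function(labels) {
  if (labels$n_core + labels$n_edge == 0) return(NA_real_)
  labels$n_core / max(labels$n_edge, 1)
}

#' Unvegetated-to-edge ratio
#'
#' Fraction of edge cells whose exposure is to unvegetated cover (open
#' water, flats, bare or developed ground); inspired by the UVVR indicator.
#' Zero by convention when a unit has no edge cells; `NA` with no marsh.
#'
#' @inheritParams area_to_edge_ratio
#' @return fraction in \[0, 1\], or `NA`.
#' @export
unvegetated_edge_ratio <- function(labels) {
  if (labels$n_core + labels$n_edge == 0) return(NA_real_)
  if (labels$n_edge == 0) return(0)
  labels$n_unveg_edge / labels$n_edge
}

#' Buffered land-cover fractions around a marsh unit
#'
#' Percent impervious, natural, and agricultural cover over all non-nodata
#' cells whose centers fall inside the unit polygon dilated by `buffer_m`.
#' Impervious percent is intensity-weighted using the per-class impervious
#' fractions of the class table; natural and agricultural percents are
#' flagged-cell shares.
#'
#' @inheritParams classify_core_edge
#' @param unit a [marsh_unit()].
#' @param buffer_m buffer distance in meters (default 150).
#' @return named numeric: `pct_impervious`, `pct_natural`,
#'   `pct_agricultural`, each in \[0, 100\] (all `NA` if no cell intersects).
#' @export
landcover_fractions <- function(landcover, class_tab = landcover$class_table,
                                unit, buffer_m = 150) {
  mask <- unit_mask(unit, landcover, buffer_m = buffer_m)
  codes <- landcover$values
  sel <- mask & !is.na(codes)
  n <- sum(sel)
  if (n == 0) {
    return(c(pct_impervious = NA_real_, pct_natural = NA_real_,
             pct_agricultural = NA_real_))
  }
  imp <- ct_flag(class_tab, "impervious_fraction")[as.character(codes[sel])]
  nat <- ct_flag(class_tab, "is_natural")[as.character(codes[sel])]
  agr <- ct_flag(class_tab, "is_agricultural")[as.character(codes[sel])]
  c(pct_impervious = 100 * sum(imp) / n,
    pct_natural = 100 * sum(nat) / n,
    pct_agricultural = 100 * sum(agr) / n)
}
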