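# Adaptive-capacity metrics: shoreline hardening and complexity, marsh
# migration under inundation scenarios, and wetland connectedness.

#' Inundation scenario depths
#'
#' The default scenario set is six depths above MHHW at one-foot steps, i.e.
#' 1..6 ft converted to meters (0.3048 ... 1.8288 m).
#'
#' @param depths_m strictly increasing positive depths in meters.
#' @return numeric vector of class `scenario_set`.
#' @export
scenario_set <- function(depths_m = (1:6) * 0.3048) {
  d <- as.numeric(depths_m)
  if (!length(d) || any(d <= 0) || any(diff(d) <= 0)) {
    stop("scenario depths must be strictly increasing and > 0")
  }
  structure(d, class = "scenario_set")
}

#' Percent hardened shoreline
#'
#' Length-weighted share of a unit's shoreline flagged as hardened
#' (armoring, rocky structures).
#'
#' @param segments list of [shoreline_segment()] belonging to one unit.
#' @return percent in \[0, 100\], or `NA` for a unit without shoreline.
#' @export
pct_hardened_shoreline <- function(segments) {
  if (!length(segments)) return(NA_real_)
  len <- vapply(segments, function(s) polyline_length(s$vertices), 0)
  hard <- vapply(segments, function(s) s$hardened, NA)
  tot <- sum(len)
  if (tot <= 0) return(NA_real_)
  100 * sum(len[hard]) / tot
}

# split a closed ring at its two most distant vertices into two open
# polylines (sinuosity of a ring is undefined by endpoints)
split_ring <- function(verts) {
  v <- verts[-nrow(verts), , drop = FALSE]   # drop duplicated closing vertex
  n <- nrow(v)
  d2 <- as.matrix(stats::dist(v))^2
  ij <- arrayInd(which.max(d2), dim(d2))
  i <- min(ij); j <- max(ij)
  a <- v[i:j, , drop = FALSE]
  b <- rbind(v[j:n, , drop = FALSE], v[1:i, , drop = FALSE])
  list(a, b)
}

is_closed_ring <- function(verts) {
  nrow(verts) >= 4 && all(verts[1, ] == verts[nrow(verts), ])
}

#' Shoreline complexity (sinuosity)
#'
#' Per open segment, sinuosity = path length / straight-line endpoint
#' distance (>= 1; 1 for a straight line).  Closed rings are split at their
#' two most distant vertices into two open segments first.  The unit value
#' is the length-weighted mean over segments; degenerate open segments with
#' coincident endpoints are skipped with a warning.
#'
#' @param segments list of [shoreline_segment()] belonging to one unit.
#' @return sinuosity >= 1, or `NA` if no usable segment remains.
#' @export
shoreline_complexity <- function(segments) {
  if (!length(segments)) return(NA_real_)
  lens <- numeric(0); sins <- numeric(0)
  for (s in segments) {
    parts <- if (is_closed_ring(s$vertices)) split_ring(s$vertices)
             else list(s$vertices)
    for (v in parts) {
      L <- polyline_length(v)
      D <- sqrt(sum((v[nrow(v), ] - v[1, ])^2))
      if (D <= 0) {
        warning("skipping degenerate shoreline segment (coincident endpoints) in unit ",
                s$unit_id)
        next
      }
      lens <- c(lens, L); sins <- c(sins, L / D)
    }
  }
  if (!length(lens)) return(NA_real_)
  sum(lens * sins) / sum(lens)
}

# connected-component labelling of a logical mask (BFS with vectorized
# frontiers); returns an integer matrix, 0 outside the mask
label_components <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- neighbor_offsets(connectivity)
  nxt <- 0L
  todo <- which(mask)
  seen <- !mask
  for (start in todo) {
    if (seen[start]) next
    nxt <- nxt + 1L
    frontier <- start
    seen[start] <- TRUE
    lab[start] <- nxt
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nbr <- integer(0)
      for (off in offs) {
        rr <- r + off[1]; cc <- c + off[2]
        keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        nbr <- c(nbr, (cc[keep] - 1L) * nr + rr[keep])
      }
      nbr <- unique(nbr[!seen[nbr]])
      if (length(nbr)) {
        seen[nbr] <- TRUE
        lab[nbr] <- nxt
        frontier <- nbr
      } else frontier <- integer(0)
    }
  }
  lab
}

# cells floodable at depth d above MHHW and hydrologically connected to
# current water/marsh: connected components over {water, marsh, elevation <
# MHHW + d} that contain water or marsh
flood_reachable <- function(wet_seed, low_enough, connectivity = 4) {
  dom <- wet_seed | low_enough
  lab <- label_components(dom, connectivity)
  wet_labs <- unique(lab[wet_seed & lab > 0L])
  lab > 0L & matrix(lab %in% wet_labs, nrow(lab), ncol(lab))
}

#' Marsh migration ratio under inundation scenarios
#'
#' For each scenario depth d above MHHW: potential future marsh are the
#' unit's migratable cells (natural upland or agriculture; developed and
#' impervious excluded) that are not currently marsh, lie at
#' MHHW <= elevation < MHHW + d, and are hydrologically connected — through
#' cells below MHHW + d, open water, or marsh — to the unit's current marsh
#' or water.  The per-depth ratio is that area over the current marsh area;
#' the metric is the mean ratio over the scenario set.
#'
#' @param landcover a [land_cover_grid()].
#' @param class_tab a [class_table()].
#' @param elevation aligned elevation [raster_grid()].
#' @param tides a [tidal_surface()].
#' @param mask logical matrix selecting the unit's cells.
#' @param scenarios a [scenario_set()].
#' @param connected require hydrologic connectivity (default `TRUE`).
#' @param connectivity 4 or 8 for the flood fill.
#' @return mean ratio >= 0, or `NA` when the unit has no current marsh.
#' @export
migration_ratio <- function(landcover, class_tab = landcover$class_table,
                            elevation, tides, mask,
                            scenarios = scenario_set(),
                            connected = TRUE, connectivity = 4) {
  marsh <- codes_to_flag(landcover$values, class_tab, "is_marsh")
  marsh[is.na(marsh)] <- FALSE
  n_marsh <- sum(marsh & mask)
  if (n_marsh == 0) return(NA_real_)
  cands <- migration_candidates(landcover, class_tab, elevation, tides,
                                scenarios, connected, connectivity)
  mean(vapply(cands, function(cand) sum(cand & mask) / n_marsh, 0))
}

# per-depth matrices of potential-future-marsh cells, shared across units:
# migratable, not currently marsh, in the [MHHW, MHHW + d) band, and (when
# `connected`) hydrologically reachable from current marsh/water
migration_candidates <- function(landcover, class_tab, elevation, tides,
                                 scenarios = scenario_set(),
                                 connected = TRUE, connectivity = 4) {
  codes <- landcover$values
  marsh <- codes_to_flag(codes, class_tab, "is_marsh"); marsh[is.na(marsh)] <- FALSE
  water <- codes_to_flag(codes, class_tab, "is_water"); water[is.na(water)] <- FALSE
  migr <- codes_to_flag(codes, class_tab, "is_migratable"); migr[is.na(migr)] <- FALSE
  idx_all <- seq_along(codes)
  mhhw <- matrix(datum_at(tides, "mhhw", idx_all), nrow(codes), ncol(codes))
  e <- elevation$values
  lapply(unclass(scenarios), function(d) {
    band <- !is.na(e) & !is.na(mhhw) & e >= mhhw & e < mhhw + d
    cand <- migr & !marsh & band
    if (connected) {
      low <- !is.na(e) & !is.na(mhhw) & e < mhhw + d
      reach <- flood_reachable(wet_seed = (marsh | water), low_enough = low,
                               connectivity = connectivity)
      cand <- cand & reach
    }
    cand
  })
}

#' Wetland connectedness across units
#'
#' Groups the marsh footprints of all units into connected complexes
#' ("region groups") under the current landscape and under a future scenario
#' at `slr` meters above MHHW (surviving marsh plus connected migration
#' space).  Within each current group the raw score is
#' (n_current_units - n_future_units) / n_current_units — larger when more
#' units drop out of the complex.  Because the framework treats
#' connectedness as a positive influence, the metric value stored per unit
#' is the negated raw score (larger = better); both are returned.
#'
#' @inheritParams migration_ratio
#' @param masks named list of unit masks (one per unit, names = unit ids).
#' @param slr future sea level rise above MHHW in meters (default 1.2).
#' @return data.frame with `unit_id`, `connectedness` (negated, larger =
#'   better), `connectedness_raw`, `current_group`; `NA` scores for units
#'   with no marsh in any scenario.
#' @export
connectedness <- function(landcover, class_tab = landcover$class_table,
                          elevation, tides, masks, slr = 1.2,
                          connectivity = 4) {
  codes <- landcover$values
  marsh <- codes_to_flag(codes, class_tab, "is_marsh"); marsh[is.na(marsh)] <- FALSE
  water <- codes_to_flag(codes, class_tab, "is_water"); water[is.na(water)] <- FALSE
  migr <- codes_to_flag(codes, class_tab, "is_migratable"); migr[is.na(migr)] <- FALSE
  e <- elevation$values
  idx_all <- seq_along(codes)
  mhhw <- matrix(datum_at(tides, "mhhw", idx_all), nrow(codes), ncol(codes))

  # future marsh footprint: current marsh that stays above the new MTL proxy
  # (not drowned below MHHW + slr is approximated as elevation >= MTL + slr),
  # plus reachable migration space in [MHHW, MHHW + slr)
  mtl <- matrix(datum_at(tides, "mtl", idx_all), nrow(codes), ncol(codes))
  surviving <- marsh & !is.na(e) & e >= mtl + slr
  band <- migr & !marsh & !is.na(e) & !is.na(mhhw) & e >= mhhw & e < mhhw + slr
  low <- !is.na(e) & !is.na(mhhw) & e < mhhw + slr
  reach <- flood_reachable(wet_seed = (marsh | water), low_enough = low,
                           connectivity = connectivity)
  future <- surviving | (band & reach)

  lab_cur <- label_components(marsh, connectivity)
  ids <- names(masks)
  # group of a unit: component(s) its marsh overlaps; units sharing a
  # component form one region group (union-find over shared components)
  unit_comps <- lapply(masks, function(m) unique(lab_cur[m & marsh & lab_cur > 0L]))
  has_marsh <- vapply(unit_comps, function(x) length(x) > 0, NA)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  comp_owner <- new.env()
  for (i in seq_along(ids)) {
    for (cmp in unit_comps[[i]]) {
      key <- as.character(cmp)
      j <- mget(key, envir = comp_owner, ifnotfound = NA)[[1]]
      if (is.na(j)) assign(key, i, envir = comp_owner)
      else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  group_of <- rep(NA_integer_, length(ids))
  for (i in seq_along(ids)) if (has_marsh[i]) group_of[i] <- find(i)

  contributes_future <- vapply(masks, function(m) any(future & m), NA)
  out <- data.frame(unit_id = ids, connectedness = NA_real_,
                    connectedness_raw = NA_real_,
                    current_group = NA_integer_, stringsAsFactors = FALSE)
  for (gid in unique(stats::na.omit(group_of))) {
    members <- which(group_of == gid)
    n_cur <- length(members)
    n_fut <- sum(contributes_future[members])
    raw <- (n_cur - n_fut) / n_cur
    out$connectedness_raw[members] <- raw
    out$connectedness[members] <- -raw
    out$current_group[members] <- gid
  }
  out
}
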