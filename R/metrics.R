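#' Compute the thirteen resilience metrics for every marsh unit
#'
#' Runs all metric engines over a [landscape()]: the five current-condition
#' metrics, the four vulnerability metrics, and the four adaptive-capacity
#' metrics, one row per marsh unit.  Units without marsh cells get missing
#' raster metrics (they are excluded from scoring downstream); units without
#' shoreline get missing shoreline metrics.
#'
#' @param ls a [landscape()].
#' @param config a [framework_config()]; supplies buffer distance,
#'   connectivity, scenario depths and the connectedness SLR.
#' @return data.frame (`metric_table`): `unit_id`, group label columns, and
#'   the 13 metric columns of [metric_columns()].
#' @examples
#' ls <- generate_landscape(seed = 1, n_units = 4, grid_shape = c(60, 60))
#' head(compute_metrics(ls))
#' @export
compute_metrics <- function(ls, config = framework_config()) {
  ct <- ls$class_table
  masks <- landscape_unit_masks(ls)
  ids <- names(masks)
  marsh <- codes_to_flag(ls$landcover$values, ct, "is_marsh")
  marsh[is.na(marsh)] <- FALSE

  seg_by_unit <- split(ls$shorelines,
                       vapply(ls$shorelines, function(s) s$unit_id, ""))
  scen <- scenario_set(config$scenarios_m)
  conn <- connectedness(ls$landcover, ct, ls$elevation, ls$tides, masks,
                        slr = config$connectedness_slr_m,
                        connectivity = config$connectivity)
  # per-depth flood fills are landscape-level; compute once, share per unit
  mig_cands <- migration_candidates(ls$landcover, ct, ls$elevation, ls$tides,
                                    scen, connected = config$migration_connected,
                                    connectivity = config$connectivity)

  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]; mask <- masks[[i]]
    mmask <- mask & marsh
    has_marsh <- any(mmask)
    if (has_marsh) {
      ce <- classify_core_edge(ls$landcover, ct, mask,
                               connectivity = config$connectivity)
      a2e <- area_to_edge_ratio(ce)
      uvr <- unvegetated_edge_ratio(ce)
    } else {
      a2e <- uvr <- NA_real_
    }
    lf <- landcover_fractions(ls$landcover, ct, ls$units[[i]],
                              buffer_m = config$buffer_m)
    segs <- seg_by_unit[[id]]
    data.frame(
      unit_id = id,
      area_to_edge_ratio = a2e,
      unveg_edge_ratio = uvr,
      pct_impervious = lf[["pct_impervious"]],
      pct_natural = lf[["pct_natural"]],
      pct_agricultural = lf[["pct_agricultural"]],
      soil_erodibility = mean_erodibility(ls$erodibility, mask),
      tidal_range_m = tidal_range(ls$tides, mask),
      pct_below_mhhw = pct_marsh_below("mhhw", ls$elevation, ls$tides, mmask),
      pct_below_mtl = pct_marsh_below("mtl", ls$elevation, ls$tides, mmask),
      pct_hardened = if (is.null(segs)) NA_real_ else pct_hardened_shoreline(segs),
      shoreline_complexity = if (is.null(segs)) NA_real_ else shoreline_complexity(segs),
      migration_ratio = if (!has_marsh) NA_real_ else {
        n_marsh <- sum(mmask)
        mean(vapply(mig_cands, function(cand) sum(cand & mask) / n_marsh, 0))
      },
      connectedness = conn$connectedness[conn$unit_id == id],
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  grp <- landscape_groups(ls)
  tab <- merge(tab, grp, by = "unit_id", sort = FALSE)
  tab[match(ids, tab$unit_id), , drop = FALSE]
}
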