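# Synthetic landscapes and metric tables.
#
# The generator states a fixed synthetic world: 30 m cells, a water->flat->
# marsh->upland elevation gradient inside each unit tile, tidal datums tied
# to elevation-field quantiles so the realized marsh fraction tracks the
# requested fraction by construction, and post-classification elevation
# jitter so elevation-relative metrics are non-degenerate.  See the methods
# vignette for the rationale behind each default.

default_landscape_params <- function() {
  list(
    cell_size = 30,          # m, matching 30 m land-cover products
    water_fraction = 0.2,    # open water + unvegetated flat share of cells
    mllw_m = -1.0,           # physical anchor for MLLW, m
    mhhw_m = 0.5,            # physical anchor for MHHW, m (range 1.5 m)
    datum_trend_m = 0.25,    # east-west amplitude of the gridded datums, m
    elev_jitter_sd = 0.15,   # per-cell elevation scatter after classing, m
    marsh_pond_p = 0.03,     # marsh cells converted to unvegetated ponds
    ag_fraction = 0.15,      # share of upland assigned to agriculture
    dev_fraction = 0.10,     # share of upland assigned to developed classes
    hardened_fraction = 0.3, # probability a shoreline segment is hardened
    segments_per_unit = 3L,
    noise_scale = 10         # coarse-field block size for smooth noise, cells
  )
}

# smooth random field in [-1, 1]-ish via coarse grid + bilinear upsampling
smooth_field <- function(nr, nc, scale) {
  cr <- max(2L, ceiling(nr / scale) + 1L)
  cc <- max(2L, ceiling(nc / scale) + 1L)
  coarse <- matrix(stats::runif(cr * cc, -1, 1), cr, cc)
  ri <- (seq_len(nr) - 0.5) / nr * (cr - 1) + 1
  ci <- (seq_len(nc) - 0.5) / nc * (cc - 1) + 1
  r0 <- pmin(floor(ri), cr - 1); c0 <- pmin(floor(ci), cc - 1)
  fr <- ri - r0; fc <- ci - c0
  a <- coarse[cbind(rep(r0, nc), rep(c0, each = nr))]
  b <- coarse[cbind(rep(r0 + 1, nc), rep(c0, each = nr))]
  d <- coarse[cbind(rep(r0, nc), rep(c0 + 1, each = nr))]
  e <- coarse[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  fr <- rep(fr, nc); fc <- rep(fc, each = nr)
  v <- a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) +
    d * (1 - fr) * fc + e * fr * fc
  matrix(v, nr, nc)
}

# split n_units into a tile lattice (rows x cols of rectangles)
tile_layout <- function(n_units) {
  kc <- ceiling(sqrt(n_units))
  kr <- ceiling(n_units / kc)
  list(kr = kr, kc = kc)
}

#' Generate a seeded synthetic landscape
#'
#' Builds a complete [landscape()]: patchy marsh bordered by water and
#' upland, an elevation surface spanning below MLLW to more than 2 m above
#' MHHW, gridded tidal datums satisfying MLLW <= MTL <= MHHW everywhere,
#' attributed shoreline polylines with a controllable hardened fraction, and
#' rectangular marsh units tiling the grid with region/state group labels.
#' Deterministic for a fixed seed and argument set.
#'
#' @param seed integer RNG seed.
#' @param n_units number of marsh units (>= 1).
#' @param grid_shape integer length-2, (rows, cols).
#' @param marsh_fraction target share of cells classified as marsh, in
#'   \[0, 1\].
#' @param params generator configuration; see `default_landscape_params()`
#'   entries (any subset may be overridden).
#' @return A [landscape()].
#' @examples
#' ls <- generate_landscape(seed = 1, n_units = 4, grid_shape = c(60, 60))
#' ls
#' @export
generate_landscape <- function(seed, n_units = 10L,
                               grid_shape = c(200L, 200L),
                               marsh_fraction = 0.3,
                               params = list()) {
  if (n_units < 1) stop("n_units must be >= 1")
  if (marsh_fraction < 0 || marsh_fraction > 1) {
    stop("marsh_fraction must lie in [0, 1]")
  }
  p <- utils::modifyList(default_landscape_params(), params)
  if (marsh_fraction + p$water_fraction > 0.95) {
    stop("marsh_fraction + water_fraction must be <= 0.95")
  }
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  lay <- tile_layout(n_units)
  tile_h <- nr %/% lay$kr; tile_w <- nc %/% lay$kc
  if (tile_h < 2 || tile_w < 2) {
    stop("grid too small: each of the ", n_units,
         " unit tiles must cover >= 4 cells")
  }
  set.seed(as.integer(seed))
  cs <- p$cell_size

  col_of <- matrix(rep(seq_len(nc), each = nr), nr)
  row_of <- matrix(rep(seq_len(nr), times = nc), nr)
  tile_col <- pmin((col_of - 1L) %/% tile_w, lay$kc - 1L)
  # fractional west->east position within each tile drives the local gradient
  u <- ((col_of - 1L) %% tile_w + 0.5) / tile_w
  u[tile_col == lay$kc - 1L] <-
    (((col_of - 1L) - (lay$kc - 1L) * tile_w + 0.5) / (nc - (lay$kc - 1L) * tile_w))[tile_col == lay$kc - 1L]
  base <- u + 0.15 * smooth_field(nr, nc, p$noise_scale)

  # datums at elevation-field quantiles => marsh band mass == marsh_fraction
  q_mllw <- stats::quantile(base, p$water_fraction * 0.6, names = FALSE)
  q_mtl  <- stats::quantile(base, p$water_fraction, names = FALSE)
  q_mhhw <- stats::quantile(base, p$water_fraction + marsh_fraction,
                            names = FALSE)
  is_water_c <- base < q_mllw
  is_flat_c  <- base >= q_mllw & base < q_mtl
  is_marsh_c <- base >= q_mtl & base < q_mhhw

  # map the base field to meters anchored at the physical datum values
  scl <- (p$mhhw_m - p$mllw_m) / max(q_mhhw - q_mllw, 1e-9)
  elev <- (base - q_mllw) * scl + p$mllw_m
  # guarantee upland reaches > MHHW + 2 m
  above <- elev > p$mhhw_m
  if (any(above)) {
    top <- max(elev[above])
    if (top < p$mhhw_m + 2.1) {
      g <- (p$mhhw_m + 2.1) / max(top - p$mhhw_m, 1e-9)
      elev[above] <- p$mhhw_m + (elev[above] - p$mhhw_m) * g
    }
  }

  # land-cover classes
  ct <- default_class_table()
  codes <- matrix(4L, nr, nc)                    # natural upland default
  codes[is_water_c] <- 1L
  codes[is_flat_c] <- 3L
  codes[is_marsh_c] <- 2L
  # interior marsh ponds: a few marsh cells become unvegetated flat
  if (p$marsh_pond_p > 0 && any(is_marsh_c)) {
    pond <- is_marsh_c & matrix(stats::runif(nr * nc), nr) < p$marsh_pond_p
    codes[pond] <- 3L
  }
  upland <- codes == 4L
  if (any(upland)) {
    agf <- smooth_field(nr, nc, p$noise_scale)
    dvf <- smooth_field(nr, nc, p$noise_scale)
    ag_thr <- stats::quantile(agf[upland], 1 - p$ag_fraction, names = FALSE)
    codes[upland & agf >= ag_thr] <- 5L
    upland2 <- codes == 4L
    if (any(upland2) && p$dev_fraction > 0) {
      dv_thr <- stats::quantile(dvf[upland2],
                                1 - p$dev_fraction / max(1 - p$ag_fraction, 1e-9),
                                names = FALSE)
      dev <- upland2 & dvf >= dv_thr
      codes[dev] <- sample(c(6L, 7L, 8L), sum(dev), replace = TRUE)
    }
  }

  # per-cell elevation scatter (lidar-like noise) after classification
  elev <- elev + stats::rnorm(nr * nc, 0, p$elev_jitter_sd)

  # gridded datums with a gentle west-east trend (ordering preserved)
  tr <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr)
  mhhw <- matrix(p$mhhw_m, nr, nc) + p$datum_trend_m * tr
  mllw <- matrix(p$mllw_m, nr, nc) - p$datum_trend_m * tr
  mtl <- (mhhw + mllw) / 2 + 0.1
  tides <- tidal_surface(mhhw = mhhw, mtl = mtl, mllw = mllw)

  landcover <- land_cover_grid(codes, ct, cell_size = cs, origin = c(0, nr * cs))
  elevation <- raster_grid(elev, cell_size = cs, origin = c(0, nr * cs))
  kfac <- pmax(0.3 + 0.15 * smooth_field(nr, nc, p$noise_scale), 0.02)
  erod <- raster_grid(kfac, cell_size = cs, origin = c(0, nr * cs))

  # units: rectangular tiles in planar meters (row-major order)
  units <- vector("list", n_units)
  region_names <- c("west", "center", "east")
  for (i in seq_len(n_units)) {
    tr_i <- (i - 1L) %/% lay$kc
    tc_i <- (i - 1L) %% lay$kc
    r0 <- tr_i * tile_h; r1 <- if (tr_i == lay$kr - 1L) nr else (tr_i + 1L) * tile_h
    c0 <- tc_i * tile_w; c1 <- if (tc_i == lay$kc - 1L) nc else (tc_i + 1L) * tile_w
    # planar corners (origin is the upper-left of the grid)
    x0 <- c0 * cs; x1 <- c1 * cs
    ytop <- (nr - r0) * cs; ybot <- (nr - r1) * cs
    bnd <- rbind(c(x0, ybot), c(x1, ybot), c(x1, ytop), c(x0, ytop))
    region <- region_names[1 + (tc_i * 3L) %/% lay$kc]
    units[[i]] <- marsh_unit(
      unit_id = sprintf("MU%03d", i), boundary = bnd,
      groups = list(region = region,
                    state = if (tr_i %% 2L == 0L) "northstate" else "southstate"))
  }

  # shorelines: wiggly polylines inside each tile, hardened with the
  # configured probability
  shorelines <- list()
  for (i in seq_len(n_units)) {
    b <- units[[i]]$boundary
    xr <- range(b[, 1]); yr <- range(b[, 2])
    for (s in seq_len(p$segments_per_unit)) {
      nv <- 12L
      xs <- seq(xr[1] + cs, xr[2] - cs, length.out = nv)
      y0 <- stats::runif(1, yr[1] + cs, yr[2] - cs)
      amp <- stats::runif(1, 0, (yr[2] - yr[1]) / 6)
      ys <- y0 + amp * sin(seq(0, 2 * pi, length.out = nv)) +
        stats::rnorm(nv, 0, cs / 4)
      ys <- pmin(pmax(ys, yr[1]), yr[2])
      shorelines[[length(shorelines) + 1L]] <- shoreline_segment(
        vertices = cbind(xs, ys),
        hardened = stats::runif(1) < p$hardened_fraction,
        unit_id = units[[i]]$unit_id)
    }
  }

  landscape(landcover, elevation, tides, erod, shorelines, units, ct)
}

# ---- synthetic metric tables ------------------------------------------------

#' Default distribution spec for synthetic metric tables
#'
#' One entry per metric column with a marginal `mean` and `sd`.  Percent
#' metrics are drawn from moment-matched beta distributions on \[0, 100\],
#' non-negative ratios from gamma, sinuosity as 1 + gamma, and connectedness
#' (oriented so larger = better) as minus a beta draw on \[-1, 0\].  The
#' cross-column constraints `pct_below_mtl <= pct_below_mhhw` and
#' `pct_natural + pct_agricultural <= 100` are enforced by drawing the
#' dependent column as a fraction of the headroom; its marginal mean is
#' preserved exactly, its sd approximately.
#'
#' @return named list of `list(mean =, sd =)` entries, one per metric.
#' @export
default_metric_spec <- function() {
  list(
    area_to_edge_ratio   = list(mean = 0.8,  sd = 0.5),
    unveg_edge_ratio     = list(mean = 0.30, sd = 0.15),
    pct_impervious       = list(mean = 8,    sd = 6),
    pct_natural          = list(mean = 55,   sd = 15),
    pct_agricultural     = list(mean = 12,   sd = 8),
    soil_erodibility     = list(mean = 0.30, sd = 0.08),
    tidal_range_m        = list(mean = 1.5,  sd = 0.8),
    pct_below_mhhw       = list(mean = 70,   sd = 15),
    pct_below_mtl        = list(mean = 20,   sd = 10),
    pct_hardened         = list(mean = 20,   sd = 15),
    shoreline_complexity = list(mean = 1.3,  sd = 0.25),
    migration_ratio      = list(mean = 0.5,  sd = 0.4),
    connectedness        = list(mean = -0.15, sd = 0.12)
  )
}

# beta draw on [0,1] with given mean/sd (sd on the same [0,1] scale)
rbeta_ms <- function(n, mean, sd) {
  if (mean < 0 || mean > 1) stop("beta mean outside [0, 1]")
  if (sd < 0) stop("negative sd")
  if (sd == 0) return(rep(mean, n))
  if (mean %in% c(0, 1)) return(rep(mean, n))
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("sd too large for a beta distribution with mean ", mean)
  }
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

rgamma_ms <- function(n, mean, sd) {
  if (mean < 0) stop("gamma mean must be >= 0")
  if (sd < 0) stop("negative sd")
  if (sd == 0 || mean == 0) return(rep(mean, n))
  stats::rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Generate a synthetic per-unit metric table
#'
#' Draws one row per synthetic unit directly on the metric scale, feeding the
#' scoring engine without any raster work.  Deterministic per seed; all
#' percent columns lie in \[0, 100\], ratios are >= 0, and the cross-column
#' constraints hold row-wise.
#'
#' @param seed integer RNG seed.
#' @param n_units number of rows (>= 1).
#' @param spec per-metric `list(mean =, sd =)`, as [default_metric_spec()];
#'   any subset may be overridden.  A negative `sd` is rejected.
#' @param groups optional character vector of group labels to cycle over the
#'   units as a `region` column (default two regions).
#' @return data.frame with `unit_id`, `region`, and the 13 metric columns of
#'   [metric_columns()].
#' @export
generate_metric_table <- function(seed, n_units,
                                  spec = default_metric_spec(),
                                  groups = c("regionA", "regionB")) {
  if (n_units < 1) stop("n_units must be >= 1")
  spec <- utils::modifyList(default_metric_spec(), spec)
  for (nm in names(spec)) {
    if (spec[[nm]]$sd < 0) stop("negative sd for metric ", nm)
  }
  set.seed(as.integer(seed))
  n <- as.integer(n_units)
  g <- function(nm) spec[[nm]]

  pct <- function(nm) 100 * rbeta_ms(n, g(nm)$mean / 100, g(nm)$sd / 100)
  tab <- data.frame(
    unit_id = sprintf("SU%04d", seq_len(n)),
    region = rep(groups, length.out = n),
    stringsAsFactors = FALSE
  )
  tab$area_to_edge_ratio <- rgamma_ms(n, g("area_to_edge_ratio")$mean,
                                      g("area_to_edge_ratio")$sd)
  tab$unveg_edge_ratio <- rbeta_ms(n, g("unveg_edge_ratio")$mean,
                                   g("unveg_edge_ratio")$sd)
  tab$pct_impervious <- pct("pct_impervious")
  tab$pct_natural <- pct("pct_natural")
  # agriculture as a fraction of the non-natural headroom: marginal mean is
  # preserved (independent factors), row-wise pct_natural + pct_ag <= 100
  ma <- g("pct_agricultural")$mean; sa <- g("pct_agricultural")$sd
  head_mean <- 100 - g("pct_natural")$mean
  frac <- rbeta_ms(n, ma / head_mean, min(sa / head_mean,
                                          0.99 * sqrt(ma / head_mean * (1 - ma / head_mean))))
  tab$pct_agricultural <- (100 - tab$pct_natural) * frac
  tab$soil_erodibility <- rgamma_ms(n, g("soil_erodibility")$mean,
                                    g("soil_erodibility")$sd)
  tab$tidal_range_m <- rgamma_ms(n, g("tidal_range_m")$mean,
                                 g("tidal_range_m")$sd)
  tab$pct_below_mhhw <- pct("pct_below_mhhw")
  mt <- g("pct_below_mtl")$mean; st <- g("pct_below_mtl")$sd
  mh <- g("pct_below_mhhw")$mean
  fr2 <- rbeta_ms(n, mt / mh, min(st / mh, 0.99 * sqrt(mt / mh * (1 - mt / mh))))
  tab$pct_below_mtl <- tab$pct_below_mhhw * fr2
  tab$pct_hardened <- pct("pct_hardened")
  sc <- g("shoreline_complexity")
  tab$shoreline_complexity <- 1 + rgamma_ms(n, sc$mean - 1, sc$sd)
  tab$migration_ratio <- rgamma_ms(n, g("migration_ratio")$mean,
                                   g("migration_ratio")$sd)
  cn <- g("connectedness")
  tab$connectedness <- -rbeta_ms(n, -cn$mean, cn$sd)
  tab
}
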