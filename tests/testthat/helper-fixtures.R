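# Tiny hand-built landscapes for geometry tests.

# a code matrix wrapped into a land_cover_grid with the default class table
make_lc <- function(codes, cell_size = 30) {
  land_cover_grid(codes, default_class_table(), cell_size = cell_size,
                  origin = c(0, nrow(codes) * cell_size))
}

# square marsh block of side s centered in a field of `bg` code
block_codes <- function(n, s, bg = 1L, marsh = 2L) {
  codes <- matrix(bg, n, n)
  o <- (n - s) %/% 2
  codes[(o + 1):(o + s), (o + 1):(o + s)] <- marsh
  codes
}

full_mask <- function(codes) matrix(TRUE, nrow(codes), ncol(codes))

# one rectangular marsh unit covering the whole grid of a land-cover grid
whole_grid_unit <- function(grid, unit_id = "U1", groups = list()) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  marsh_unit(unit_id,
             rbind(c(0, 0), c(nc * cs, 0), c(nc * cs, nr * cs), c(0, nr * cs)),
             groups = groups)
}

# a straight horizontal shoreline segment of given length
straight_segment <- function(len, hardened = FALSE, unit_id = "U1", y = 0) {
  shoreline_segment(cbind(c(0, len), c(y, y)), hardened, unit_id)
}

# a metric table with every column constant except chosen overrides
constant_metric_table <- function(n, overrides = list()) {
  mc <- metric_columns()$all
  tab <- data.frame(unit_id = sprintf("U%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  base <- c(area_to_edge_ratio = 1, unveg_edge_ratio = 0.3,
            pct_impervious = 10, pct_natural = 50, pct_agricultural = 10,
            soil_erodibility = 0.3, tidal_range_m = 1.5,
            pct_below_mhhw = 60, pct_below_mtl = 20, pct_hardened = 20,
            shoreline_complexity = 1.2, migration_ratio = 0.5,
            connectedness = -0.1)
  for (m in mc) tab[[m]] <- rep(base[[m]], n)
  for (m in names(overrides)) tab[[m]] <- overrides[[m]]
  tab
}

# random metric table with distinct values everywhere (no ties)
random_metric_table <- function(n, seed) {
  set.seed(seed)
  tab <- data.frame(unit_id = sprintf("U%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  tab$area_to_edge_ratio <- stats::runif(n, 0, 5)
  tab$unveg_edge_ratio <- stats::runif(n)
  tab$pct_impervious <- stats::runif(n, 0, 100)
  tab$pct_natural <- stats::runif(n, 0, 60)
  tab$pct_agricultural <- stats::runif(n, 0, 40)
  tab$soil_erodibility <- stats::runif(n, 0, 0.6)
  tab$tidal_range_m <- stats::runif(n, 0, 4)
  tab$pct_below_mhhw <- stats::runif(n, 0, 100)
  tab$pct_below_mtl <- tab$pct_below_mhhw * stats::runif(n)
  tab$pct_hardened <- stats::runif(n, 0, 100)
  tab$shoreline_complexity <- 1 + stats::runif(n, 0, 2)
  tab$migration_ratio <- stats::runif(n, 0, 3)
  tab$connectedness <- -stats::runif(n)
  tab
}
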