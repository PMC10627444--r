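test_that("scenario sets validate and default to six one-foot steps", {
  s <- scenario_set()
  expect_equal(unclass(s), (1:6) * 0.3048, tolerance = 1e-12)
  expect_error(scenario_set(c(0.5, 0.5)), "increasing")
  expect_error(scenario_set(c(-0.1, 0.5)), "increasing|> 0")
})

test_that("percent hardened shoreline is length-weighted", {
  segs <- list(straight_segment(30, hardened = TRUE),
               straight_segment(90, hardened = FALSE))
  expect_equal(pct_hardened_shoreline(segs), 25)
  expect_equal(pct_hardened_shoreline(list(straight_segment(10, TRUE))), 100)
  expect_true(is.na(pct_hardened_shoreline(list())))
})

test_that("pct hardened is invariant under collinear splitting", {
  whole <- list(shoreline_segment(cbind(c(0, 100), c(0, 0)), TRUE, "U1"),
                shoreline_segment(cbind(c(0, 60), c(10, 10)), FALSE, "U1"))
  split3 <- list(
    shoreline_segment(cbind(c(0, 40), c(0, 0)), TRUE, "U1"),
    shoreline_segment(cbind(c(40, 70), c(0, 0)), TRUE, "U1"),
    shoreline_segment(cbind(c(70, 100), c(0, 0)), TRUE, "U1"),
    shoreline_segment(cbind(c(0, 60), c(10, 10)), FALSE, "U1"))
  expect_equal(pct_hardened_shoreline(whole), pct_hardened_shoreline(split3))
})

test_that("sinuosity reproduces the geometric reference cases", {
  expect_equal(shoreline_complexity(list(straight_segment(50))), 1)
  # 3-4-5 right angle: path 7, chord 5
  elbow <- shoreline_segment(rbind(c(0, 0), c(3, 0), c(3, 4)), FALSE, "U1")
  expect_equal(shoreline_complexity(list(elbow)), 1.4)
  # fine semicircular arc converges to pi/2
  th <- seq(0, pi, length.out = 100)
  arc <- shoreline_segment(cbind(cos(th), sin(th)), FALSE, "U1")
  expect_equal(shoreline_complexity(list(arc)), pi / 2, tolerance = 0.01)
  # length-weighted mean over mixed segments
  mix <- list(straight_segment(50), elbow)
  expect_equal(shoreline_complexity(mix), (50 * 1 + 7 * 1.4) / 57)
})

test_that("sinuosity >= 1 always, closed rings are split, degenerates warn", {
  set.seed(4)
  for (i in 1:10) {
    verts <- cbind(cumsum(runif(8, 0.5, 2)), rnorm(8))
    s <- shoreline_complexity(list(shoreline_segment(verts, FALSE, "U")))
    expect_gte(s, 1)
  }
  # closed square ring: two halves, each with sinuosity 2s / (s*sqrt(2))
  ring <- shoreline_segment(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10),
                                  c(0, 0)), FALSE, "U1")
  expect_equal(shoreline_complexity(list(ring)), sqrt(2), tolerance = 1e-12)
  # open polyline with coincident endpoints is skipped with a warning
  loopish <- shoreline_segment(rbind(c(0, 0), c(1, 1), c(0, 0)), FALSE, "U1")
  expect_warning(res <- shoreline_complexity(list(loopish, straight_segment(5))),
                 "degenerate")
  expect_equal(res, 1)
})

# a 1-row landscape: 10 marsh cells, 5 migratable flat cells just above
# MHHW, the rest high upland
migration_fixture <- function(flat_elev = 0.65, high = 6) {
  codes <- matrix(c(rep(2L, 10), rep(4L, 5), rep(4L, 5)), nrow = 1)
  lc <- make_lc(codes)
  elev <- matrix(c(rep(0.0, 10), rep(flat_elev, 5), rep(high, 5)), nrow = 1)
  list(lc = lc, elev = raster_grid(elev, 30, origin = c(0, 30)),
       tides = tidal_surface(mhhw = 0.5, mtl = 0.0, mllw = -0.7))
}

test_that("migration ratio reproduces the forced scenarios", {
  fx <- migration_fixture(flat_elev = 0.65)   # MHHW + 0.15
  mask <- matrix(TRUE, 1, 20)
  r <- migration_ratio(fx$lc, elevation = fx$elev, tides = fx$tides,
                       mask = mask)
  expect_equal(r, 0.5)   # 5 cells flood in every scenario / 10 marsh cells

  # everything above MHHW + 1.9 m: nothing inundates
  fx2 <- migration_fixture(flat_elev = 0.5 + 1.9)
  expect_equal(migration_ratio(fx2$lc, elevation = fx2$elev,
                               tides = fx2$tides, mask = mask), 0)

  # zero current marsh -> missing
  lc_nomarsh <- make_lc(matrix(4L, 1, 20))
  expect_true(is.na(migration_ratio(lc_nomarsh, elevation = fx$elev,
                                    tides = fx$tides, mask = mask)))
})

test_that("developed cells are excluded and connectivity gates the fill", {
  # marsh | developed wall | low migratable flat behind the wall
  codes <- matrix(c(rep(2L, 5), 8L, rep(4L, 4)), nrow = 1)
  lc <- make_lc(codes)
  elev <- raster_grid(matrix(c(rep(0, 5), 5, rep(0.6, 4)), nrow = 1), 30,
                      origin = c(0, 30))
  tides <- tidal_surface(0.5, 0, -0.7)
  mask <- matrix(TRUE, 1, 10)
  # wall blocks the hydrologic path
  expect_equal(migration_ratio(lc, elevation = elev, tides = tides,
                               mask = mask, connected = TRUE), 0)
  # unconnected fill ignores the wall
  expect_equal(migration_ratio(lc, elevation = elev, tides = tides,
                               mask = mask, connected = FALSE), 4 / 5)
  # the developed wall cell itself is never migration space
  elev2 <- raster_grid(matrix(c(rep(0, 5), 0.6, rep(0.6, 4)), nrow = 1), 30,
                       origin = c(0, 30))
  expect_equal(migration_ratio(lc, elevation = elev2, tides = tides,
                               mask = mask, connected = TRUE), 4 / 5)
})

test_that("terraced ramp matches hand-enumerated per-depth flood fills", {
  # terraces at MHHW + {0.15, 0.45, 0.75, 1.05, 1.35, 1.65}: one new cell
  # floods per one-foot scenario step
  mhhw <- 0.5
  heights <- mhhw + c(0.15, 0.45, 0.75, 1.05, 1.35, 1.65)
  codes <- matrix(c(2L, 2L, rep(4L, 6)), nrow = 1)
  lc <- make_lc(codes)
  elev <- raster_grid(matrix(c(0, 0, heights), nrow = 1), 30, origin = c(0, 30))
  tides <- tidal_surface(mhhw, 0, -0.7)
  mask <- matrix(TRUE, 1, 8)
  depths <- (1:6) * 0.3048
  expected <- mean(sapply(depths, function(d) sum(heights < mhhw + d) / 2))
  expect_equal(migration_ratio(lc, elevation = elev, tides = tides,
                               mask = mask), expected)
})

test_that("migration ratio is monotone non-decreasing in scenario depth", {
  for (seed in 1:5) {
    ls <- generate_landscape(seed = seed, n_units = 4, grid_shape = c(40, 40))
    mask <- unit_mask(ls$units[[1]], ls$landcover)
    depths <- c(0.2, 0.5, 0.9, 1.4, 2.0)
    vals <- sapply(depths, function(d) {
      migration_ratio(ls$landcover, elevation = ls$elevation,
                      tides = ls$tides, mask = mask,
                      scenarios = scenario_set(d))
    })
    if (any(is.na(vals))) next
    expect_true(all(diff(vals) >= -1e-12), label = paste("seed", seed))
  }
})

# four 1-column units over a 4-cell marsh strip joined along a row
connected_fixture <- function(drown_last = FALSE) {
  # 3 rows x 4 cols: middle row marsh, top water, bottom upland
  codes <- rbind(rep(1L, 4), rep(2L, 4), rep(4L, 4))
  lc <- make_lc(codes)
  cs <- lc$cell_size
  marsh_elev <- rep(2.0, 4)       # stays above MTL + 1.2 -> survives
  if (drown_last) marsh_elev[4] <- 0.1
  elev <- rbind(rep(-1, 4), marsh_elev, rep(6, 4))
  if (drown_last) elev[3, 4] <- 6  # no migration space for the last unit
  tides <- tidal_surface(0.5, 0, -0.7)
  units <- lapply(1:4, function(i) {
    marsh_unit(paste0("U", i),
               rbind(c((i - 1) * cs, 0), c(i * cs, 0), c(i * cs, 3 * cs),
                     c((i - 1) * cs, 3 * cs)))
  })
  masks <- lapply(units, unit_mask, grid = lc)
  names(masks) <- paste0("U", 1:4)
  list(lc = lc, elev = raster_grid(elev, cs, origin = c(0, 3 * cs)),
       tides = tides, masks = masks)
}

test_that("connectedness: persistent groups score zero", {
  fx <- connected_fixture()
  res <- connectedness(fx$lc, elevation = fx$elev, tides = fx$tides,
                       masks = fx$masks, slr = 1.2)
  expect_equal(res$connectedness, rep(0, 4))
  expect_equal(res$connectedness_raw, rep(0, 4))
  expect_length(unique(res$current_group), 1)

  # single isolated unit whose marsh persists
  one <- connected_fixture()
  res1 <- connectedness(one$lc, elevation = one$elev, tides = one$tides,
                        masks = one$masks["U1"], slr = 1.2)
  expect_equal(res1$connectedness, 0)
})

test_that("connectedness: a dropped-out unit yields raw 0.25, stored -0.25", {
  fx <- connected_fixture(drown_last = TRUE)
  res <- connectedness(fx$lc, elevation = fx$elev, tides = fx$tides,
                       masks = fx$masks, slr = 1.2)
  expect_equal(res$connectedness_raw, rep(0.25, 4))
  expect_equal(res$connectedness, rep(-0.25, 4))
})

test_that("component labelling agrees with a union-find oracle", {
  set.seed(6)
  for (i in 1:5) {
    mask <- matrix(runif(30 * 30) < 0.45, 30, 30)
    for (conn in c(4, 8)) {
      got <- marshres:::label_components(mask, conn)
      exp <- oracle_components(mask, conn)
      # same partition: labels must be a bijection
      expect_equal(max(got), max(exp))
      key <- paste(got[mask], exp[mask])
      expect_equal(length(unique(key)), max(got))
    }
  }
})
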